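# Independent brute-force oracles. These deliberately share no code with
# the package: plain-loop dynamic programming and window scans, usable only
# at small problem sizes.

# Ends-free (overlap) global alignment with match +1 / mismatch -1 /
# linear gap -1. Returns the optimal score and the min/max number of
# matched columns over *all* co-optimal alignments, via a forward/backward
# DP and a second pass restricted to optimal edges.
oracle_overlap_align <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  sub <- function(i, j) if (A[i] == B[j]) 1 else -1
  FF <- matrix(-Inf, m + 1, n + 1)
  FF[1, ] <- 0; FF[, 1] <- 0
  for (i in 1:m) for (j in 1:n) {
    FF[i + 1, j + 1] <- max(FF[i, j] + sub(i, j),
                            FF[i, j + 1] - 1, FF[i + 1, j] - 1)
  }
  BK <- matrix(-Inf, m + 1, n + 1)
  BK[m + 1, ] <- 0; BK[, n + 1] <- 0
  for (i in m:1) for (j in n:1) {
    BK[i, j] <- max(sub(i, j) + BK[i + 1, j + 1],
                    BK[i + 1, j] - 1, BK[i, j + 1] - 1)
  }
  opt <- max(FF + BK)
  on_opt <- (FF + BK) == opt
  MX <- matrix(-Inf, m + 1, n + 1)
  MN <- matrix(Inf, m + 1, n + 1)
  for (r in (m + 1):1) for (c in (n + 1):1) {
    if (!on_opt[r, c]) next
    cand_max <- c(); cand_min <- c()
    if (r == m + 1 || c == n + 1) {
      if (BK[r, c] == 0) { cand_max <- 0; cand_min <- 0 }
    }
    if (r <= m && c <= n &&
        sub(r, c) + BK[r + 1, c + 1] == BK[r, c] && on_opt[r + 1, c + 1]) {
      is_m <- as.integer(A[r] == B[c])
      cand_max <- c(cand_max, is_m + MX[r + 1, c + 1])
      cand_min <- c(cand_min, is_m + MN[r + 1, c + 1])
    }
    if (r <= m && BK[r + 1, c] - 1 == BK[r, c] && on_opt[r + 1, c]) {
      cand_max <- c(cand_max, MX[r + 1, c])
      cand_min <- c(cand_min, MN[r + 1, c])
    }
    if (c <= n && BK[r, c + 1] - 1 == BK[r, c] && on_opt[r, c + 1]) {
      cand_max <- c(cand_max, MX[r, c + 1])
      cand_min <- c(cand_min, MN[r, c + 1])
    }
    if (length(cand_max)) {
      MX[r, c] <- max(cand_max)
      MN[r, c] <- min(cand_min)
    }
  }
  starts <- which((row(FF) == 1 | col(FF) == 1) & BK == opt & MX > -Inf)
  list(score = opt,
       nmatch_min = min(MN[starts]),
       nmatch_max = max(MX[starts]))
}

# Smith-Waterman local alignment score with BLOSUM62 and affine gaps
# (a gap of length L costs open + L * ext), three-state DP.
oracle_local_score <- function(a, b, open = 10, ext = 1) {
  submat <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                envir = e); e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  H <- E <- FF <- matrix(0, m + 1, n + 1)
  E[] <- -Inf; FF[] <- -Inf
  best <- 0
  for (i in 1:m) for (j in 1:n) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
    FF[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, FF[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + submat[A[i], B[j]],
                           E[i + 1, j + 1], FF[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# Plain six-frame start-to-stop ORF scanner (loop-based, one ORF per stop,
# first start after the previous stop).
oracle_orfs <- function(seq, min_aa_len,
                        starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  scan1 <- function(s, strand, L) {
    out <- list()
    for (f in 0:2) {
      i <- f + 1
      cur_start <- NA
      while (i + 2 <= nchar(s)) {
        codon <- substr(s, i, i + 2)
        if (is.na(cur_start) && codon %in% starts) cur_start <- i
        if (codon %in% stops) {
          if (!is.na(cur_start)) {
            aa_len <- (i - cur_start) / 3
            if (aa_len >= min_aa_len) {
              st <- cur_start; en <- i + 2
              if (strand == "-") { tmp <- st; st <- L - en + 1; en <- L - tmp + 1 }
              out[[length(out) + 1]] <- data.frame(
                start = st, end = en, strand = strand)
            }
          }
          cur_start <- NA
        }
        i <- i + 3
      }
    }
    out
  }
  L <- nchar(seq)
  rows <- c(scan1(seq, "+", L), scan1(revcomp(seq), "-", L))
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), ]
}

# Sliding-window overlapping match counter for a fixed-width degenerate
# pattern given as a regex.
oracle_count_matches <- function(aa, pattern, width) {
  n <- nchar(aa)
  if (n < width) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - width + 1)) {
    if (grepl(paste0("^", pattern, "$"), substr(aa, i, i + width - 1))) {
      hits <- c(hits, i)
    }
  }
  hits
}

# All DPXG(18)DPXG windows with at most max_mm mismatches over the six
# conserved positions, checked residue by residue.
oracle_dpxg_all <- function(aa, max_mm) {
  n <- nchar(aa)
  res <- integer(0)
  if (n < 26) return(res)
  for (i in seq_len(n - 25)) {
    w <- substr(aa, i, i + 25)
    mm <- sum(c(substr(w, 1, 1) != "D", substr(w, 2, 2) != "P",
                substr(w, 4, 4) != "G", substr(w, 23, 23) != "D",
                substr(w, 24, 24) != "P", substr(w, 26, 26) != "G"))
    if (mm <= max_mm) res <- c(res, i)
  }
  res
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# Small, fast simulation used across test files.
small_sim_config <- function(seed = 11, ...) {
  defaults <- list(n_strains = 4, pool_size = 8,
                   loci_per_strain_range = c(2, 2),
                   orphans_per_locus_range = c(2, 3),
                   n_decoy_orfs = 5, n_housekeeping = 3,
                   short_domain_controls = 1, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Detection chain on one strain of a simulation.
detect_strain <- function(sim, strain, min_aa_len = 100) {
  g <- call_rhs_genes(sim$genomes[strain], min_aa_len = min_aa_len)
  classify_architecture(assemble_loci(g))
}
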