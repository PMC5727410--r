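#' Default degenerate YD-repeat pattern
#'
#' A position-degenerate stand-in for the Rhs core repeat: 16 residues with
#' the G/Y/YD/GRL anchor positions conserved and the rest free. Supplied as a
#' fixed-width regular expression so matches can overlap.
#' @return Character scalar (regular expression, width 16).
#' @export
rhs_repeat_pattern <- function() "..G..Y.YD..GRL.."

#' Default PAAR motif pattern
#' @return Character scalar (regular expression).
#' @export
paar_pattern <- function() "PAAR[PS]"

## All (overlapping) matches of a fixed-width pattern; returns starts and the
## matched width.
.pattern_hits <- function(aa, pattern) {
  if (!nzchar(pattern)) stop("empty pattern")
  m <- gregexpr(paste0("(?=(", pattern, "))"), aa, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(starts = integer(0), width = 0L))
  width <- attr(m, "capture.length")[1, 1]
  list(starts = as.integer(m), width = as.integer(width))
}

#' Scan a protein for the Rhs core repeat region
#'
#' Counts (possibly overlapping) matches of a degenerate repeat pattern and,
#' when at least \code{min_repeats} are found, reports the span from the
#' first to the last match.
#'
#' @param aa_seq Protein sequence (character scalar).
#' @param repeat_pattern Fixed-width degenerate pattern
#'   (default \code{\link{rhs_repeat_pattern}()}).
#' @param min_repeats Minimum number of repeat matches.
#' @return List with \code{start}, \code{end} (1-based residue positions) and
#'   \code{n_repeats}, or \code{NULL} when fewer than \code{min_repeats}
#'   matches exist.
#' @export
scan_rhs_core <- function(aa_seq, repeat_pattern = rhs_repeat_pattern(),
                          min_repeats = 4) {
  hits <- .pattern_hits(aa_seq, repeat_pattern)
  n <- length(hits$starts)
  if (n < min_repeats) return(NULL)
  list(start = hits$starts[1],
       end = hits$starts[n] + hits$width - 1L,
       n_repeats = n)
}

#' Detect a PAAR motif in a protein
#'
#' @param aa_seq Protein sequence.
#' @param pattern Degenerate motif pattern (default
#'   \code{\link{paar_pattern}()}).
#' @return List with \code{start}, \code{end} of the first match, or
#'   \code{NULL}.
#' @export
detect_paar <- function(aa_seq, pattern = paar_pattern()) {
  hits <- .pattern_hits(aa_seq, pattern)
  if (length(hits$starts) == 0L) return(NULL)
  list(start = hits$starts[1], end = hits$starts[1] + hits$width - 1L)
}

#' Call Rhs-family genes in a genome
#'
#' Finds ORFs, keeps those whose translation carries at least
#' \code{min_repeats} copies of the core repeat, locates the PAAR motif and
#' the DPXG(18)DPXG core/toxin boundary, and flags pseudogenes: an Rhs ORF
#' whose own translation lacks the motif but whose in-frame extension past
#' the stop codon contains it has been interrupted by a nonsense mutation.
#'
#' @param genome Named character vector or
#'   \code{\link[Biostrings]{DNAStringSet}} of contigs (names become contig
#'   ids), or a single sequence.
#' @param min_aa_len Minimum ORF length considered (residues).
#' @param repeat_pattern,min_repeats Passed to \code{\link{scan_rhs_core}}.
#' @param paar Pattern passed to \code{\link{detect_paar}}.
#' @param mode Motif stringency for \code{\link{locate_dpxg}}.
#' @param max_extension_nt Cap on the in-frame extension read past an ORF's
#'   stop codon when testing for pseudogenisation.
#' @return \code{data.frame}, one row per Rhs gene: ORF columns plus
#'   \code{has_paar}, \code{core_start}, \code{core_end}, \code{n_repeats},
#'   \code{motif_start}, \code{motif_end} (residue coordinates within the
#'   protein; NA when absent) and \code{pseudogene}.
#' @export
call_rhs_genes <- function(genome, min_aa_len = 100,
                           repeat_pattern = rhs_repeat_pattern(),
                           min_repeats = 4, paar = paar_pattern(),
                           mode = c("default", "stringent"),
                           max_extension_nt = 3000) {
  mode <- match.arg(mode)
  genome <- .as_named_seqs(genome)
  rows <- list()
  for (ci in seq_along(genome)) {
    contig_id <- names(genome)[ci]
    cseq <- as.character(genome[[ci]])
    orfs <- find_orfs(cseq, min_aa_len = min_aa_len, contig_id = contig_id)
    if (nrow(orfs) == 0L) next
    for (i in seq_len(nrow(orfs))) {
      core <- scan_rhs_core(orfs$aa[i], repeat_pattern, min_repeats)
      if (is.null(core)) next
      row <- orfs[i, ]
      pa <- detect_paar(orfs$aa[i], paar)
      row$has_paar <- !is.null(pa)
      row$core_start <- core$start
      row$core_end <- core$end
      row$n_repeats <- core$n_repeats
      motif <- locate_dpxg(orfs$aa[i], mode = mode)
      pseudo <- FALSE
      if (is.null(motif)) {
        ext <- .inframe_extension(cseq, row$start, row$end, row$strand,
                                  max_extension_nt)
        if (nzchar(ext$aa) && !is.null(locate_dpxg(ext$aa, mode = mode))) {
          pseudo <- TRUE
        }
        row$motif_start <- NA_integer_
        row$motif_end <- NA_integer_
      } else {
        row$motif_start <- motif$start
        row$motif_end <- motif$end
        if (motif$end <= core$end) {
          ## motif must lie past the repeat region to delimit a toxin domain
          row$motif_start <- NA_integer_
          row$motif_end <- NA_integer_
        }
      }
      row$pseudogene <- pseudo
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) return(.empty_rhs_table())
  out <- do.call(rbind, rows)
  out$gene_id <- sprintf("%s_rhs%02d", out$contig,
                         stats::ave(seq_len(nrow(out)), out$contig,
                                    FUN = seq_along))
  rownames(out) <- NULL
  out
}

.empty_rhs_table <- function() {
  cbind(.empty_orf_table(),
        data.frame(has_paar = logical(0), core_start = integer(0),
                   core_end = integer(0), n_repeats = integer(0),
                   motif_start = integer(0), motif_end = integer(0),
                   pseudogene = logical(0), gene_id = character(0)))
}

.as_named_seqs <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) {
      names(genome) <- sprintf("contig%02d", seq_along(genome))
    }
    return(genome)
  }
  genome <- as.character(genome)
  if (is.null(names(genome))) {
    names(genome) <- sprintf("contig%02d", seq_along(genome))
  }
  Biostrings::DNAStringSet(genome)
}

## Translate the co-frame continuation of an ORF past its stop codon, up to
## the next in-frame stop (or the cap / contig end).
.inframe_extension <- function(contig_seq, start, end, strand,
                               max_extension_nt = 3000) {
  L <- nchar(contig_seq)
  if (strand == "+") {
    from <- end + 1L
    to <- min(L, end + max_extension_nt)
    if (from > to - 2L) return(list(aa = "", nt = ""))
    seg <- substr(contig_seq, from, to)
  } else {
    to <- start - 1L
    from <- max(1L, start - max_extension_nt)
    if (from > to - 2L) return(list(aa = "", nt = ""))
    seg <- .revcomp(substr(contig_seq, from, to))
  }
  n_codons <- nchar(seg) %/% 3L
  if (n_codons == 0L) return(list(aa = "", nt = ""))
  seg <- substr(seg, 1L, 3L * n_codons)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seg),
                                           if.fuzzy.codon = "X"))
  stop_pos <- regexpr("\\*", aa)
  if (stop_pos > 0L) aa <- substr(aa, 1L, stop_pos - 1L)
  list(aa = aa, nt = substr(seg, 1L, 3L * nchar(aa)))
}

#' Group Rhs genes into loci
#'
#' Consecutive Rhs genes on the same contig separated by at most
#' \code{max_gap_nt} form one locus. Genes are numbered 5' to 3' in the
#' orientation of the locus, taken from its lead (PAAR-bearing) gene, or the
#' first gene when no lead is present.
#'
#' @param genes Rhs gene table from \code{\link{call_rhs_genes}}.
#' @param max_gap_nt Maximum intergenic distance within a locus.
#' @return The input with \code{locus_id} and \code{position_in_locus}
#'   (0-based) columns added.
#' @export
assemble_loci <- function(genes, max_gap_nt = 5000) {
  if (nrow(genes) == 0L) {
    genes$locus_id <- character(0)
    genes$position_in_locus <- integer(0)
    return(genes)
  }
  ord <- order(genes$contig, genes$start)
  genes <- genes[ord, , drop = FALSE]
  gap_break <- c(TRUE, genes$contig[-1] != genes$contig[-nrow(genes)] |
                   (genes$start[-1] - genes$end[-nrow(genes)]) > max_gap_nt)
  locus_no <- cumsum(gap_break)
  genes$locus_id <- sprintf("%s_L%02d", genes$contig,
                            stats::ave(locus_no, genes$contig,
                                       FUN = function(x) match(x, unique(x))))
  genes$position_in_locus <- NA_integer_
  for (lid in unique(genes$locus_id)) {
    idx <- which(genes$locus_id == lid)
    lead <- idx[genes$has_paar[idx]]
    ori <- if (length(lead)) genes$strand[lead[1]] else genes$strand[idx[1]]
    pos <- if (ori == "+") seq_along(idx) - 1L else rev(seq_along(idx) - 1L)
    genes$position_in_locus[idx] <- pos
  }
  rownames(genes) <- NULL
  genes
}

#' Classify Rhs gene architecture
#'
#' Labels each gene as \code{lead} (PAAR motif plus full core),
#' \code{orphan} (no PAAR, toxin domain present), \code{toxinless} (no
#' core/toxin boundary motif), \code{n_truncated} (repeat count below
#' \code{trunc_frac} of the locus lead's count) or \code{pseudogene}
#' (overrides everything else).
#'
#' @param genes Rhs gene table with locus assignments
#'   (\code{\link{assemble_loci}}).
#' @param trunc_frac Fraction of the lead gene's repeat count below which a
#'   core counts as N-terminally truncated.
#' @return The input with an \code{architecture} column added.
#' @export
classify_architecture <- function(genes, trunc_frac = 0.6) {
  if (nrow(genes) == 0L) {
    genes$architecture <- character(0)
    return(genes)
  }
  ref_repeats <- vapply(seq_len(nrow(genes)), function(i) {
    idx <- which(genes$locus_id == genes$locus_id[i])
    lead <- idx[genes$has_paar[idx] & !genes$pseudogene[idx]]
    if (length(lead)) max(genes$n_repeats[lead]) else max(genes$n_repeats[idx])
  }, numeric(1))
  has_motif <- !is.na(genes$motif_end)
  arch <- ifelse(genes$pseudogene, "pseudogene",
          ifelse(!has_motif, "toxinless",
          ifelse(genes$n_repeats < trunc_frac * ref_repeats, "n_truncated",
          ifelse(genes$has_paar, "lead", "orphan"))))
  genes$architecture <- arch
  genes
}
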