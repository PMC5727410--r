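#' Transcripts per million
#'
#' Length-normalised expression: counts are divided by gene length, scaled
#' so each replicate (column) sums to one million.
#'
#' @param counts Integer matrix (genes x replicates); a vector is treated as
#'   one replicate.
#' @param lengths_nt Gene lengths in nucleotides, parallel to rows.
#' @return Numeric matrix of TPM values, same shape as \code{counts}.
#' @export
tpm <- function(counts, lengths_nt) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  stopifnot(nrow(counts) == length(lengths_nt), all(lengths_nt > 0),
            all(counts >= 0))
  rate <- counts / lengths_nt
  tot <- colSums(rate)
  if (any(tot == 0)) stop("tpm: replicate with all-zero counts")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Spearman rank correlation with a t-approximation p value
#'
#' Ranks (average ranks for ties), Pearson correlation of the ranks, and a
#' two-sided p value from \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on
#' \code{n - 2} degrees of freedom. Used for the gene-position versus
#' expression trend along a locus.
#'
#' @param x,y Paired numeric vectors, \code{n >= 3}.
#' @return List: \code{rho}, \code{p}, \code{n}. With a constant input
#'   vector the correlation is undefined and both values are NA.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("spearman_correlation: need n >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' One-way ANOVA with Tukey's HSD
#'
#' Classical one-way analysis of variance followed by Tukey's honestly
#' significant difference comparisons (Tukey-Kramer for unequal group
#' sizes), as used to compare Rhs gene counts between T6SS complement
#' groups.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, parallel to \code{values}; at least two
#'   groups, every group non-empty.
#' @return List: \code{F}, \code{p}, \code{df}, and \code{tukey}, a
#'   \code{data.frame} with \code{comparison}, \code{diff}, \code{lwr},
#'   \code{upr}, \code{p_adj}.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("anova_tukey: need at least two groups")
  if (any(table(groups) == 0)) stop("anova_tukey: empty group")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = s[["F value"]][1],
       p = s[["Pr(>F)"]][1],
       df = s[["Df"]],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE))
}

## ---- Nei-Gojobori (1986) dN/dS -------------------------------------------

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- list(aa = gc, codons = names(gc),
                   sense = names(gc)[gc != "*"])
    }
    tab
  }
})

## Synonymous site count of one codon: at each position, the fraction of the
## three possible changes that are synonymous, mutations to stop codons
## excluded from the denominator.
.syn_sites <- function(codon, gc) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    alts <- vapply(setdiff(bases, substr(codon, p, p)), function(b) {
      alt <- codon
      substr(alt, p, p) <- b
      alt
    }, character(1))
    aa_alt <- gc[alts]
    valid <- aa_alt != "*"
    if (!any(valid)) next
    s <- s + sum(aa_alt[valid] == gc[[codon]]) / sum(valid)
  }
  s
}

## Synonymous/nonsynonymous difference counts between two codons, averaged
## over all mutational pathways; pathways through stop codons are dropped
## (unless every pathway is blocked, in which case all are kept).
.codon_diffs <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else
    if (k == 2L) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                  c(3,2,1)), function(o) pos[o])
  paths <- lapply(perms, function(ord) {
    cur <- c1
    steps <- matrix(0, nrow = length(ord), ncol = 2)
    blocked <- FALSE
    for (j in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[j], ord[j]) <- substr(c2, ord[j], ord[j])
      if (gc[[nxt]] == "*" && j < length(ord)) blocked <- TRUE
      steps[j, ] <- c(gc[[cur]] == gc[[nxt]], gc[[cur]] != gc[[nxt]])
      cur <- nxt
    }
    list(sd = sum(steps[, 1]), nd = sum(steps[, 2]), blocked = blocked)
  })
  open <- !vapply(paths, `[[`, logical(1), "blocked")
  if (any(open)) paths <- paths[open]
  c(sd = mean(vapply(paths, `[[`, numeric(1), "sd")),
    nd = mean(vapply(paths, `[[`, numeric(1), "nd")))
}

#' Nei-Gojobori (1986) dN/dS for a pair of aligned coding sequences
#'
#' Counting-method estimate of synonymous and nonsynonymous divergence:
#' synonymous/nonsynonymous site counts averaged over the two sequences,
#' pathway-averaged difference counts, Jukes-Cantor correction
#' \code{d = -3/4 log(1 - 4/3 p)}, and \code{omega = dN/dS}. Codon columns
#' containing gaps, ambiguity characters or stop codons are skipped.
#'
#' @param seq1,seq2 In-frame aligned nucleotide sequences of equal length
#'   (gaps as \code{-}).
#' @return List: \code{dN}, \code{dS}, \code{omega}, site and difference
#'   counts (\code{N}, \code{S}, \code{Nd}, \code{Sd}), \code{n_codons}
#'   used, and \code{status}: \code{"ok"}, \code{"identical"} (omega
#'   undefined, no differences), \code{"dS_zero"} (omega undefined/infinite)
#'   or \code{"saturated"} (Jukes-Cantor correction impossible).
#' @export
ng86_dnds <- function(seq1, seq2) {
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) %% 3 == 0)
  gc <- .codon_table()$aa
  sense <- .codon_table()$sense
  pos <- 3L * (seq_len(nchar(seq1) %/% 3L) - 1L) + 1L
  cod1 <- substring(seq1, pos, pos + 2L)
  cod2 <- substring(seq2, pos, pos + 2L)
  use <- cod1 %in% sense & cod2 %in% sense
  if (!any(use)) stop("ng86_dnds: no ungapped sense codon columns")
  cod1 <- cod1[use]; cod2 <- cod2[use]
  syn_cache <- new.env()
  syn <- function(codon) {
    if (is.null(syn_cache[[codon]])) {
      syn_cache[[codon]] <- .syn_sites(codon, gc)
    }
    syn_cache[[codon]]
  }
  S <- (sum(vapply(cod1, syn, numeric(1))) +
        sum(vapply(cod2, syn, numeric(1)))) / 2
  N <- 3 * length(cod1) - S
  diff_idx <- which(cod1 != cod2)
  Sd <- Nd <- 0
  for (i in diff_idx) {
    d <- .codon_diffs(cod1[i], cod2[i], gc)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  res <- list(dN = NA_real_, dS = NA_real_, omega = NA_real_,
              N = N, S = S, Nd = Nd, Sd = Sd, n_codons = length(cod1),
              status = "ok")
  if (Sd == 0 && Nd == 0) {
    res$dN <- 0; res$dS <- 0; res$status <- "identical"
    return(res)
  }
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  pN <- Nd / N; pS <- Sd / S
  res$dN <- jc(pN); res$dS <- jc(pS)
  if (is.na(res$dN) || is.na(res$dS)) {
    res$status <- "saturated"
  } else if (res$dS == 0) {
    res$status <- "dS_zero"
  } else {
    res$omega <- res$dN / res$dS
  }
  res
}

## ---- Distance trees and congruence ---------------------------------------

#' Pairwise p-distance matrix for aligned sequences
#'
#' Proportion of differing sites between every pair, positions with gaps or
#' \code{N} in either sequence excluded pairwise.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1, !is.null(names(seqs)))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  good <- mat %in% c("A", "C", "G", "T")
  dim(good) <- dim(mat)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- good[i, ] & good[j, ]
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else NA_real_
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}); on an additive matrix it
#' recovers the generating topology and branch lengths.
#'
#' @param d Symmetric distance matrix (or \code{dist}) over >= 3 taxa.
#' @return Unrooted \code{phylo} tree.
#' @export
nj_tree <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (attr(d, "Size") < 3) stop("nj_tree: need at least 3 taxa")
  ape::nj(d)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two unrooted trees;
#' 0 means topological congruence. Leaf sets must match.
#'
#' @param tree1,tree2 \code{phylo} objects (or newick strings).
#' @return Integer.
#' @export
rf_distance <- function(tree1, tree2) {
  if (is.character(tree1)) tree1 <- ape::read.tree(text = tree1)
  if (is.character(tree2)) tree2 <- ape::read.tree(text = tree2)
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("rf_distance: trees have different leaf sets")
  }
  as.integer(ape::dist.topo(ape::unroot(tree1), ape::unroot(tree2),
                            method = "PH85"))
}
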