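#' Locate the DPXG(18)DPXG core/toxin boundary motif
#'
#' The motif is two DPxG tetrads separated by exactly 18 arbitrary residues
#' (26 residues in total); it terminates the conserved Rhs core, and the
#' toxin domain starts immediately after it. In \code{default} mode one
#' mismatch is tolerated across the six conserved positions (D, P, G twice);
#' \code{stringent} mode requires all six. When several windows qualify the
#' most C-terminal one is returned, consistent with the motif marking the
#' end of the core.
#'
#' @param aa_seq Protein sequence (character scalar, non-empty).
#' @param mode \code{"default"} (<= 1 mismatch) or \code{"stringent"} (0).
#' @return List with \code{start}, \code{end} (residue positions, inclusive;
#'   \code{end - start == 25}) and \code{mismatches}, or \code{NULL}.
#' @export
locate_dpxg <- function(aa_seq, mode = c("default", "stringent")) {
  mode <- match.arg(mode)
  stopifnot(nzchar(aa_seq))
  max_mm <- if (mode == "default") 1L else 0L
  n <- nchar(aa_seq)
  if (n < 26L) return(NULL)
  idx <- seq_len(n - 25L)
  ch <- function(off) substring(aa_seq, idx + off, idx + off)
  mm <- (ch(0L) != "D") + (ch(1L) != "P") + (ch(3L) != "G") +
        (ch(22L) != "D") + (ch(23L) != "P") + (ch(25L) != "G")
  ok <- which(mm <= max_mm)
  if (length(ok) == 0L) return(NULL)
  i <- ok[length(ok)]
  list(start = i, end = i + 25L, mismatches = as.integer(mm[i]))
}

#' Extract C-terminal toxin domains
#'
#' For each Rhs gene with a located DPXG(18)DPXG motif, the toxin domain is
#' the in-frame suffix starting at the residue after the motif and ending
#' before the stop codon. Domains shorter than the length filter are
#' dropped: 40 nt in \code{default} mode, 200 nt in \code{stringent} mode
#' (override with \code{min_nt}).
#'
#' @param genes Rhs gene table from \code{\link{call_rhs_genes}} (needs
#'   \code{gene_id}, \code{nt}, \code{aa}, \code{motif_end}).
#' @param mode Length-filter/motif stringency regime.
#' @param min_nt Optional explicit length floor in nucleotides.
#' @return \code{data.frame} with one row per gene: \code{gene_id},
#'   \code{start_aa} (first toxin residue), \code{nt}, \code{aa},
#'   \code{length_nt}, \code{mode} and \code{status} (\code{"ok"},
#'   \code{"no_motif"} or \code{"too_short"}).
#' @export
extract_cterm <- function(genes, mode = c("default", "stringent"),
                          min_nt = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_nt)) min_nt <- if (mode == "default") 40L else 200L
  n <- nrow(genes)
  out <- data.frame(gene_id = genes$gene_id,
                    start_aa = NA_integer_, nt = NA_character_,
                    aa = NA_character_, length_nt = 0L,
                    mode = mode, status = "no_motif",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    me <- genes$motif_end[i]
    if (is.na(me)) next
    if (mode == "stringent") {
      ## re-evaluate the motif without mismatch tolerance
      m <- locate_dpxg(genes$aa[i], mode = "stringent")
      if (is.null(m)) next
      me <- m$end
    }
    aa_len <- nchar(genes$aa[i])
    start_aa <- me + 1L
    dom_aa <- if (start_aa > aa_len) "" else
      substr(genes$aa[i], start_aa, aa_len)
    dom_nt <- if (start_aa > aa_len) "" else
      substr(genes$nt[i], 3L * me + 1L, 3L * aa_len)
    out$start_aa[i] <- start_aa
    out$length_nt[i] <- nchar(dom_nt)
    if (nchar(dom_nt) < min_nt) {
      out$status[i] <- "too_short"
    } else {
      out$nt[i] <- dom_nt
      out$aa[i] <- dom_aa
      out$status[i] <- "ok"
    }
  }
  out
}

#' Extract the conserved core of each Rhs gene
#'
#' The core runs from the first repeat match to the end of the
#' DPXG(18)DPXG motif, or to the last full codon of the protein for
#' toxinless genes. Together with \code{\link{extract_cterm}} this
#' partitions the protein: core end and toxin start are adjacent residues.
#'
#' @param genes Rhs gene table from \code{\link{call_rhs_genes}}.
#' @return \code{data.frame} with \code{gene_id}, \code{start_aa},
#'   \code{end_aa}, \code{nt}, \code{aa}.
#' @export
extract_core <- function(genes) {
  n <- nrow(genes)
  out <- data.frame(gene_id = genes$gene_id,
                    start_aa = NA_integer_, end_aa = NA_integer_,
                    nt = NA_character_, aa = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cs <- genes$core_start[i]
    if (is.na(cs)) next
    ce <- if (!is.na(genes$motif_end[i])) genes$motif_end[i]
          else nchar(genes$aa[i])
    out$start_aa[i] <- cs
    out$end_aa[i] <- ce
    out$aa[i] <- substr(genes$aa[i], cs, ce)
    out$nt[i] <- substr(genes$nt[i], 3L * (cs - 1L) + 1L, 3L * ce)
  }
  out
}
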