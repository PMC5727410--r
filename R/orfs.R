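#' Find open reading frames in a nucleotide sequence
#'
#' Scans all six frames for maximal start-to-stop ORFs. Within each frame,
#' one ORF is reported per stop codon: the longest, i.e. the one beginning at
#' the first start codon after the previous in-frame stop. Reverse-strand
#' ORFs are reported in forward coordinates with \code{strand == "-"}.
#' Coordinates are 1-based and inclusive, and include the stop codon; the
#' translated protein excludes it.
#'
#' @param contig Nucleotide sequence over A/C/G/T/N (character or
#'   \code{\link[Biostrings]{DNAString}}).
#' @param min_aa_len Minimum protein length (residues, excluding the stop);
#'   must be >= 1.
#' @param start_codons Allowed initiator codons.
#' @param contig_id Value for the \code{contig} column of the result.
#' @return \code{data.frame} with columns \code{orf_id}, \code{contig},
#'   \code{start}, \code{end}, \code{strand}, \code{nt}, \code{aa},
#'   \code{aa_len}, sorted by \code{start}.
#' @export
find_orfs <- function(contig, min_aa_len = 50,
                      start_codons = c("ATG", "GTG", "TTG"),
                      contig_id = "contig") {
  seq <- toupper(as.character(contig))
  if (!nzchar(seq)) return(.empty_orf_table())
  if (grepl("[^ACGTN]", seq)) {
    stop("find_orfs: sequence contains non-nucleotide characters")
  }
  stopifnot(min_aa_len >= 1)

  fwd <- .scan_strand(seq, min_aa_len, start_codons)
  rev <- .scan_strand(.revcomp(seq), min_aa_len, start_codons)
  L <- nchar(seq)
  out <- rbind(
    if (nrow(fwd)) cbind(fwd, strand = "+"),
    if (nrow(rev)) {
      s <- L - rev$end + 1L; e <- L - rev$start + 1L
      rev$start <- s; rev$end <- e
      cbind(rev, strand = "-")
    })
  if (is.null(out) || nrow(out) == 0L) return(.empty_orf_table())
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$contig <- contig_id
  out$orf_id <- sprintf("%s_orf%03d", contig_id, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("orf_id", "contig", "start", "end", "strand", "nt", "aa", "aa_len")]
}

.empty_orf_table <- function() {
  data.frame(orf_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             nt = character(0), aa = character(0), aa_len = integer(0),
             stringsAsFactors = FALSE)
}

.STOPS <- c("TAA", "TAG", "TGA")

## One strand, coordinates local to `seq`. Vectorised over codons per frame.
.scan_strand <- function(seq, min_aa_len, start_codons) {
  L <- nchar(seq)
  res <- vector("list", 3L)
  for (f in 0:2) {
    n_codons <- (L - f) %/% 3L
    if (n_codons < min_aa_len + 1L) next
    pos <- f + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, pos, pos + 2L)
    stop_idx <- which(codons %in% .STOPS)
    if (length(stop_idx) == 0L) next
    start_idx <- which(codons %in% start_codons)
    if (length(start_idx) == 0L) next
    prev_stop <- c(0L, stop_idx[-length(stop_idx)])
    ## first start strictly after the previous stop, before this stop
    first_after <- findInterval(prev_stop, start_idx) + 1L
    orf_start <- ifelse(first_after <= length(start_idx),
                        start_idx[first_after], NA_integer_)
    keep <- !is.na(orf_start) & orf_start < stop_idx &
      (stop_idx - orf_start) >= min_aa_len
    if (!any(keep)) next
    s_codon <- orf_start[keep]; e_codon <- stop_idx[keep]
    s_nt <- f + 1L + 3L * (s_codon - 1L)
    e_nt <- f + 3L * e_codon
    nt <- substring(seq, s_nt, e_nt)
    res[[f + 1L]] <- data.frame(start = s_nt, end = e_nt, nt = nt,
                                stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), nt = character(0),
                      aa = character(0), aa_len = integer(0)))
  }
  out <- do.call(rbind, res)
  aa_full <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(out$nt), if.fuzzy.codon = "X"))
  out$aa <- substr(aa_full, 1L, nchar(aa_full) - 1L)  # drop stop
  out$aa_len <- nchar(out$aa)
  out
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
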