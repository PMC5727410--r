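#' Nucleotide identity between two sequences
#'
#' Identity is defined the way incremental clustering tools define it: the
#' number of identical aligned positions in the optimal alignment divided by
#' the length of the shorter sequence. The alignment is semi-global (end gaps
#' free on both sequences) so that a truncated copy of a domain still scores
#' near 1 against the full-length sequence; internal gaps are penalised.
#' Scoring is match +1, mismatch -1, linear gap -1 per position.
#'
#' @param a,b Nucleotide sequences (character scalars or
#'   \code{\link[Biostrings]{DNAString}}).
#' @return Identity fraction in \[0, 1\]; symmetric in its arguments.
#' @examples
#' pairwise_identity("ACGTACGTAC", "ACGTACGTAC")  # 1.0
#' pairwise_identity("ACGTACGTAC", "ACGAACGTAC")  # 0.9
#' @export
pairwise_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) {
    stop("pairwise_identity: sequences must be non-empty")
  }
  identity_to_set(Biostrings::DNAStringSet(a), b)
}

## Identities of each sequence in `set` against a single subject, batched in
## one pairwiseAlignment call. Normalisation is by the shorter sequence of
## each pair.
identity_to_set <- function(set, subject) {
  subject <- as.character(subject)
  if (length(set) == 0L) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    pattern = set, subject = subject,
    substitutionMatrix = .nt_submat(),
    gapOpening = 0, gapExtension = 1,
    type = "overlap")
  Biostrings::nmatch(aln) / pmin(Biostrings::width(set), nchar(subject))
}

.nt_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    }
    m
  }
})

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Best protein hit of a query against a proteome
#'
#' Local (Smith-Waterman) alignment of an amino-acid query against every
#' protein in a target set, keeping the highest-scoring hit. Identity is
#' identical positions over alignment columns; coverage is the fraction of
#' query residues inside the aligned region. Together they give the
#' identity-times-coverage presence score used for homolog screening.
#'
#' Targets much shorter than \code{cov_min * qlen} cannot reach the coverage
#' floor and are skipped before alignment.
#'
#' @param query Amino-acid sequence (character or
#'   \code{\link[Biostrings]{AAString}}).
#' @param proteome Named \code{\link[Biostrings]{AAStringSet}} (or named
#'   character vector) of target proteins.
#' @param id_min,cov_min Floors below which the hit is reported absent.
#' @param gap_opening,gap_extension Affine gap penalties (BLOSUM62 scoring).
#' @return A list with \code{target_id}, \code{identity}, \code{coverage},
#'   \code{score} (identity x coverage) and \code{aln_score}, or \code{NULL}
#'   when no target passes the floors.
#' @export
best_hit <- function(query, proteome, id_min = 0, cov_min = 0,
                     gap_opening = 10, gap_extension = 1) {
  query <- as.character(query)
  if (!nzchar(query)) stop("best_hit: empty query")
  if (!methods::is(proteome, "AAStringSet")) {
    proteome <- Biostrings::AAStringSet(proteome)
  }
  if (length(proteome) == 0L) stop("best_hit: empty proteome")
  qlen <- nchar(query)

  keep <- seq_along(proteome)
  if (cov_min > 0) {
    ## a target of length L can cover at most ~L query residues
    keep <- which(Biostrings::width(proteome) >= 0.5 * cov_min * qlen)
    if (length(keep) == 0L) return(NULL)
  }
  cand <- proteome[keep]

  scores <- Biostrings::pairwiseAlignment(
    pattern = cand, subject = query,
    substitutionMatrix = .blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "local", scoreOnly = TRUE)
  best <- which.max(scores)

  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = cand[[best]],
    substitutionMatrix = .blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "local")
  ncols <- Biostrings::nchar(aln)
  if (ncols == 0L) return(NULL)
  identity <- Biostrings::nmatch(aln) / ncols
  qr <- Biostrings::pattern(aln)
  coverage <- (Biostrings::end(qr) - Biostrings::start(qr) + 1L) / qlen
  if (identity < id_min || coverage < cov_min) return(NULL)
  list(target_id = names(cand)[best],
       identity = identity,
       coverage = coverage,
       score = identity * coverage,
       aln_score = Biostrings::score(aln))
}
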