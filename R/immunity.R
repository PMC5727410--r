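#' Pair Rhs toxins with downstream immunity genes
#'
#' Immunity genes have essentially no shared sequence signature, but they sit
#' immediately downstream of (and co-oriented with) their cognate toxin.
#' For every Rhs gene that carries a toxin domain (or is a pseudogenised
#' toxin), the nearest same-strand ORF starting within
#' \code{max_intergenic_nt} of the toxin's 3' end -- and not itself an Rhs
#' gene -- is called as its immunity gene. Toxinless genes get no call.
#'
#' @param genes Classified Rhs gene table (\code{\link{assemble_loci}} +
#'   \code{\link{classify_architecture}}).
#' @param orfs ORF table for the same contigs (\code{\link{find_orfs}}).
#' @param max_intergenic_nt Maximum distance from toxin stop to immunity
#'   start.
#' @return \code{data.frame}: \code{toxin_id}, \code{immunity_id} (NA when
#'   unpaired), \code{distance_nt}, \code{immunity_start},
#'   \code{immunity_end}, \code{immunity_aa}, \code{architecture}.
#' @export
pair_immunity <- function(genes, orfs, max_intergenic_nt = 200) {
  eligible <- genes[genes$architecture != "toxinless", , drop = FALSE]
  n <- nrow(eligible)
  out <- data.frame(toxin_id = eligible$gene_id,
                    immunity_id = NA_character_,
                    distance_nt = NA_integer_,
                    immunity_start = NA_integer_,
                    immunity_end = NA_integer_,
                    immunity_aa = NA_character_,
                    architecture = eligible$architecture,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  rhs_keys <- paste(genes$contig, genes$start, genes$end, genes$strand)
  orf_keys <- paste(orfs$contig, orfs$start, orfs$end, orfs$strand)
  cand_orfs <- orfs[!(orf_keys %in% rhs_keys), , drop = FALSE]
  for (i in seq_len(n)) {
    g <- eligible[i, ]
    same <- cand_orfs$contig == g$contig & cand_orfs$strand == g$strand
    if (g$strand == "+") {
      d <- cand_orfs$start - g$end
    } else {
      d <- g$start - cand_orfs$end
    }
    ok <- which(same & d >= 1L & d <= max_intergenic_nt)
    if (length(ok) == 0L) next
    ## nearest start; ties broken by ORF length
    best <- ok[order(d[ok], -(cand_orfs$end[ok] - cand_orfs$start[ok]))][1]
    out$immunity_id[i] <- cand_orfs$orf_id[best]
    out$distance_nt[i] <- d[best] - 1L
    out$immunity_start[i] <- cand_orfs$start[best]
    out$immunity_end[i] <- cand_orfs$end[best]
    out$immunity_aa[i] <- cand_orfs$aa[best]
  }
  out
}

#' Find orphan immunity genes
#'
#' Screens a genome's ORFs against a reference set of immunity proteins
#' (local alignment at identity and coverage floors, coverage measured on
#' the reference). Hits with no intact cognate toxin immediately upstream
#' are flagged as orphans -- immunity genes whose toxin has been lost or
#' pseudogenised. Each orphan is additionally tested for pseudogenisation
#' against its reference homolog.
#'
#' @param orfs ORF table of the genome (\code{\link{find_orfs}}).
#' @param reference_immunity Named \code{AAStringSet} (or named character) of
#'   reference immunity proteins.
#' @param genes Classified Rhs gene table for the same genome.
#' @param genome The genome sequences (for the pseudogene frame test).
#' @param id_threshold,cov_threshold Homology floors.
#' @param max_intergenic_nt "Immediately upstream" distance.
#' @return \code{data.frame}: \code{orf_id}, \code{reference_id},
#'   \code{identity}, \code{coverage}, \code{orphan}, \code{pseudogene}.
#' @export
find_orphan_immunity <- function(orfs, reference_immunity, genes, genome,
                                 id_threshold = 0.70, cov_threshold = 0.70,
                                 max_intergenic_nt = 200) {
  if (!methods::is(reference_immunity, "AAStringSet")) {
    reference_immunity <- Biostrings::AAStringSet(reference_immunity)
  }
  if (length(reference_immunity) == 0L) {
    stop("find_orphan_immunity: empty reference set")
  }
  genome <- .as_named_seqs(genome)
  out <- data.frame(orf_id = character(0), reference_id = character(0),
                    identity = numeric(0), coverage = numeric(0),
                    orphan = logical(0), pseudogene = logical(0),
                    stringsAsFactors = FALSE)
  if (nrow(orfs) == 0L) return(out)
  ## immunity-sized ORFs only; references set the plausible length window
  rng <- range(Biostrings::width(reference_immunity))
  cand <- orfs[orfs$aa_len >= 0.3 * rng[1] & orfs$aa_len <= 2.5 * rng[2], ,
               drop = FALSE]
  rhs_keys <- paste(genes$contig, genes$start, genes$end, genes$strand)
  cand <- cand[!(paste(cand$contig, cand$start, cand$end, cand$strand) %in%
                   rhs_keys), , drop = FALSE]
  if (nrow(cand) == 0L) return(out)
  intact <- genes[genes$architecture %in% c("lead", "orphan", "n_truncated") &
                    !genes$pseudogene, , drop = FALSE]
  ## one batched local alignment per reference against every candidate ORF
  cand_set <- Biostrings::AAStringSet(stats::setNames(cand$aa, cand$orf_id))
  best_ref <- rep(NA_character_, nrow(cand))
  best_id <- best_cov <- rep(NA_real_, nrow(cand))
  best_score <- rep(-Inf, nrow(cand))
  for (ri in seq_along(reference_immunity)) {
    ref_aa <- as.character(reference_immunity[[ri]])
    aln <- Biostrings::pairwiseAlignment(
      pattern = cand_set, subject = ref_aa,
      substitutionMatrix = .blosum62(),
      gapOpening = 10, gapExtension = 1, type = "local")
    ncols <- Biostrings::nchar(aln)
    identity <- ifelse(ncols > 0, Biostrings::nmatch(aln) / ncols, 0)
    sr <- Biostrings::subject(aln)
    coverage <- (Biostrings::end(sr) - Biostrings::start(sr) + 1L) /
      nchar(ref_aa)
    sc <- Biostrings::score(aln)
    pass <- identity >= id_threshold & coverage >= cov_threshold &
      sc > best_score
    best_ref[pass] <- names(reference_immunity)[ri]
    best_id[pass] <- identity[pass]
    best_cov[pass] <- coverage[pass]
    best_score[pass] <- sc[pass]
  }
  for (i in which(!is.na(best_ref))) {
    o <- cand[i, ]
    hit <- list(reference_id = best_ref[i], identity = best_id[i],
                coverage = best_cov[i])
    ## is an intact toxin immediately upstream (same strand)?
    if (o$strand == "+") {
      d <- o$start - intact$end
      up <- intact$contig == o$contig & intact$strand == "+" &
        d >= 1L & d <= max_intergenic_nt
    } else {
      d <- intact$start - o$end
      up <- intact$contig == o$contig & intact$strand == "-" &
        d >= 1L & d <= max_intergenic_nt
    }
    if (any(up)) next
    ref_aa <- as.character(reference_immunity[[hit$reference_id]])
    ps <- flag_pseudogene(o, ref_aa,
                          as.character(genome[[o$contig]]))
    out <- rbind(out, data.frame(
      orf_id = o$orf_id, reference_id = hit$reference_id,
      identity = hit$identity, coverage = hit$coverage,
      orphan = TRUE,
      pseudogene = isTRUE(ps$pseudogene),
      stringsAsFactors = FALSE))
  }
  out
}

#' Test an ORF for pseudogenisation against a full-length homolog
#'
#' Reads the ORF's reading frame from its start codon for as many codons as
#' the homolog is long and reports TRUE when a stop codon interrupts the
#' frame before 90% of the homolog length is reached. The ORF's own
#' terminating stop therefore counts as a lesion when the ORF is a truncated
#' fragment of the homolog. Homologs no longer than the ORF give FALSE;
#' frames running off the contig, or ORFs with no recognisable similarity to
#' the homolog, are indeterminate (NA).
#'
#' @param orf One-row ORF table (or list with \code{start}, \code{end},
#'   \code{strand}, \code{aa}).
#' @param full_length_homolog_aa Protein sequence of the intact homolog.
#' @param contig_seq Sequence of the ORF's contig.
#' @param min_identity Floor of local-alignment identity below which the
#'   comparison is indeterminate.
#' @return List with \code{pseudogene} (TRUE/FALSE/NA) and \code{lesions}
#'   (codon indices of premature stops).
#' @export
flag_pseudogene <- function(orf, full_length_homolog_aa, contig_seq,
                            min_identity = 0.3) {
  hlen <- nchar(full_length_homolog_aa)
  olen <- nchar(orf$aa)
  if (hlen <= olen) return(list(pseudogene = FALSE, lesions = integer(0)))
  hit <- best_hit(orf$aa, Biostrings::AAStringSet(
    c(homolog = full_length_homolog_aa)))
  if (is.null(hit) || hit$identity < min_identity) {
    return(list(pseudogene = NA, lesions = integer(0)))
  }
  need_nt <- 3L * hlen
  L <- nchar(contig_seq)
  if (orf$strand == "+") {
    if (orf$start + need_nt - 1L > L) {
      return(list(pseudogene = NA, lesions = integer(0)))
    }
    frame <- substr(contig_seq, orf$start, orf$start + need_nt - 1L)
  } else {
    if (orf$end - need_nt + 1L < 1L) {
      return(list(pseudogene = NA, lesions = integer(0)))
    }
    frame <- .revcomp(substr(contig_seq, orf$end - need_nt + 1L, orf$end))
  }
  pos <- 3L * (seq_len(hlen) - 1L) + 1L
  codons <- substring(frame, pos, pos + 2L)
  cutoff <- ceiling(0.9 * hlen)
  lesions <- which(codons %in% .STOPS)
  lesions <- lesions[lesions < cutoff]
  list(pseudogene = length(lesions) >= 1L, lesions = lesions)
}
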