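#' Query-by-genome presence matrix
#'
#' For every query protein and every genome, records the best local-alignment
#' hit against the genome's ORF proteome: identity, query coverage, their
#' product (the heatmap score) and a presence call at the identity/coverage
#' floors. Per-query threshold overrides support genes that need a stricter
#' cutoff than the rest of the panel.
#'
#' @param queries Named \code{AAStringSet} (or named character) of query
#'   proteins.
#' @param proteomes Named list of proteomes, one per genome, each a named
#'   \code{AAStringSet}/character vector of ORF translations.
#' @param id_min,cov_min Default presence floors.
#' @param overrides Optional named list: \code{overrides[[query_id]]} is a
#'   list/vector with elements \code{id} and/or \code{cov}.
#' @return Long-format \code{data.frame} (\code{query}, \code{genome},
#'   \code{target_id}, \code{identity}, \code{coverage}, \code{score},
#'   \code{present}); \code{attr(, "score_matrix")} holds the query-by-genome
#'   score matrix.
#' @export
presence_matrix <- function(queries, proteomes, id_min = 0.50,
                            cov_min = 0.50, overrides = list()) {
  if (!methods::is(queries, "AAStringSet")) {
    queries <- Biostrings::AAStringSet(queries)
  }
  qn <- names(queries)
  gn <- names(proteomes)
  rows <- vector("list", length(qn) * length(gn))
  k <- 0L
  for (g in gn) {
    prot <- proteomes[[g]]
    if (!methods::is(prot, "AAStringSet")) {
      prot <- Biostrings::AAStringSet(prot)
    }
    for (q in qn) {
      idm <- id_min; covm <- cov_min
      ov <- overrides[[q]]
      if (!is.null(ov)) {
        if (!is.null(ov[["id"]])) idm <- ov[["id"]]
        if (!is.null(ov[["cov"]])) covm <- ov[["cov"]]
      }
      hit <- if (length(prot)) {
        best_hit(as.character(queries[[q]]), prot)
      } else NULL
      k <- k + 1L
      rows[[k]] <- if (is.null(hit)) {
        data.frame(query = q, genome = g, target_id = NA_character_,
                   identity = 0, coverage = 0, score = 0, present = FALSE,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(query = q, genome = g, target_id = hit$target_id,
                   identity = hit$identity, coverage = hit$coverage,
                   score = hit$score,
                   present = hit$identity >= idm & hit$coverage >= covm,
                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  m <- matrix(0, nrow = length(qn), ncol = length(gn),
              dimnames = list(qn, gn))
  m[cbind(out$query, out$genome)] <- out$score
  attr(out, "score_matrix") <- m
  out
}

#' Call T6SS status per genome
#'
#' A secretion system is \code{present} in a genome when at least
#' \code{min_frac} of its core genes are present in the presence matrix,
#' \code{partial} when some but fewer are, and \code{absent} otherwise.
#'
#' @param pm Long presence table from \code{\link{presence_matrix}}.
#' @param systems Named list; each element is the character vector of core
#'   gene (query) ids of one system.
#' @param min_frac Fraction of core genes required for \code{present}.
#' @return \code{data.frame}: \code{genome}, \code{system},
#'   \code{n_present}, \code{n_core}, \code{status}.
#' @export
t6ss_status <- function(pm, systems, min_frac = 0.8) {
  genomes <- unique(pm$genome)
  out <- expand.grid(genome = genomes, system = names(systems),
                     stringsAsFactors = FALSE)
  out$n_present <- 0L
  out$n_core <- 0L
  out$status <- "absent"
  for (i in seq_len(nrow(out))) {
    core <- systems[[out$system[i]]]
    sub <- pm[pm$genome == out$genome[i] & pm$query %in% core, ]
    np <- sum(sub$present)
    out$n_present[i] <- np
    out$n_core[i] <- length(core)
    out$status[i] <- if (np >= min_frac * length(core)) "present"
                     else if (np > 0) "partial" else "absent"
  }
  out
}

#' Toxin/immunity co-occurrence screen
#'
#' Screens genomes for each reference toxin domain and its cognate immunity
#' protein at (by default) 70% identity and 70% coverage, the regime under
#' which toxin and immunity genes are expected to travel together: immunity
#' without toxin (an orphan) is tolerated, toxin without immunity is a
#' violation.
#'
#' @param pairs \code{data.frame} with \code{pair_id}, \code{toxin_aa},
#'   \code{immunity_aa}. Toxinless reference genes (no domain, hence no
#'   immunity partner) must be excluded by the caller; rows with NA in
#'   either sequence are rejected.
#' @param proteomes Named list of genome proteomes (as in
#'   \code{\link{presence_matrix}}).
#' @param id_min,cov_min Presence floors applied to both partners.
#' @return \code{data.frame}: \code{pair_id}, \code{genome},
#'   \code{toxin_present}, \code{immunity_present}, \code{violation}
#'   (toxin without immunity).
#' @export
toxin_immunity_cooccurrence <- function(pairs, proteomes, id_min = 0.70,
                                        cov_min = 0.70) {
  if (anyNA(pairs$toxin_aa) || anyNA(pairs$immunity_aa)) {
    stop("toxin_immunity_cooccurrence: pairs with missing sequences; ",
         "exclude toxinless genes first")
  }
  rows <- list()
  for (g in names(proteomes)) {
    prot <- proteomes[[g]]
    if (!methods::is(prot, "AAStringSet")) {
      prot <- Biostrings::AAStringSet(prot)
    }
    for (i in seq_len(nrow(pairs))) {
      tox <- !is.null(best_hit(pairs$toxin_aa[i], prot,
                               id_min = id_min, cov_min = cov_min))
      imm <- !is.null(best_hit(pairs$immunity_aa[i], prot,
                               id_min = id_min, cov_min = cov_min))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[i], genome = g,
        toxin_present = tox, immunity_present = imm,
        violation = tox && !imm, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mean normalised identity between two gene sets
#'
#' For each query gene of one locus, finds its best hit in the other locus's
#' gene set; the hit's identity is normalised by the fraction of the query
#' that aligned (identity times coverage), and the mean over matched genes
#' is returned. Genes with no hit above the permissive floor are skipped;
#' with no matches at all the result is absent (NA).
#'
#' @param locus_a,locus_b Named \code{AAStringSet}/character vectors of the
#'   two loci's proteins (queries are \code{locus_a}).
#' @param floor_identity,floor_coverage Permissive floors a hit must clear
#'   to count as a match.
#' @return List with \code{mean_identity} (NA when no gene matched),
#'   \code{n_matched}, \code{n_skipped}, \code{per_gene} data.frame.
#' @export
interlocus_mean_identity <- function(locus_a, locus_b,
                                     floor_identity = 0.35,
                                     floor_coverage = 0.35) {
  if (!methods::is(locus_a, "AAStringSet")) {
    locus_a <- Biostrings::AAStringSet(locus_a)
  }
  if (!methods::is(locus_b, "AAStringSet")) {
    locus_b <- Biostrings::AAStringSet(locus_b)
  }
  per <- data.frame(query = names(locus_a), value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(locus_a)) {
    hit <- best_hit(as.character(locus_a[[i]]), locus_b,
                    id_min = floor_identity, cov_min = floor_coverage)
    if (!is.null(hit)) per$value[i] <- hit$identity * hit$coverage
  }
  matched <- !is.na(per$value)
  list(mean_identity = if (any(matched)) mean(per$value[matched]) else NA_real_,
       n_matched = sum(matched), n_skipped = sum(!matched), per_gene = per)
}

#' Per-strain Rhs counts grouped by T6SS complement
#'
#' Counts Rhs genes per strain and labels each strain by which secretion
#' systems it carries, the grouping used to test whether Rhs repertoire size
#' tracks a particular T6SS.
#'
#' @param genes Rhs gene table with a \code{strain} column (rows are genes).
#' @param status Status table from \code{\link{t6ss_status}} with systems
#'   named \code{t6ss1} and \code{t6ss23}.
#' @param strains Optional character vector of all strains (so strains with
#'   zero Rhs genes are kept).
#' @return \code{data.frame}: \code{strain}, \code{n_rhs}, \code{group}
#'   (one of \code{"both"}, \code{"t6ss1_only"}, \code{"t6ss23_only"},
#'   \code{"neither"}).
#' @export
rhs_count_by_t6ss_group <- function(genes, status, strains = NULL) {
  if (is.null(strains)) strains <- unique(status$genome)
  counts <- table(factor(genes$strain, levels = strains))
  has <- function(strain, sys) {
    st <- status$status[status$genome == strain & status$system == sys]
    length(st) == 1L && st == "present"
  }
  grp <- vapply(strains, function(s) {
    a <- has(s, "t6ss1"); b <- has(s, "t6ss23")
    if (a && b) "both" else if (a) "t6ss1_only"
    else if (b) "t6ss23_only" else "neither"
  }, character(1))
  data.frame(strain = strains, n_rhs = as.integer(counts), group = grp,
             stringsAsFactors = FALSE, row.names = NULL)
}
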