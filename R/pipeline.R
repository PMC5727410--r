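#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow in one list: the
#' simulation (or ingest) settings, the detection parameters, the
#' thresholds quoted throughout the package (0.70/0.70 toxin-immunity
#' screening, 0.90 clustering identity, 40/200-nt domain filters, 5-kb
#' locus gap, 200-nt immunity distance) and the seed. Serialisable to YAML.
#'
#' @param seed Integer seed for the whole run.
#' @param simulate List of overrides for \code{\link{simulation_config}},
#'   or \code{NULL} to ingest genomes from \code{input_dir}.
#' @param input_dir Directory of genome FASTA files (ingest mode).
#' @param metadata Path to a strain metadata TSV (ingest mode; columns
#'   \code{strain_id}, \code{species}, \code{host}, \code{region}).
#' @param thresholds Named list; see Details for defaults.
#' @param domain_mode \code{"default"} or \code{"stringent"}.
#' @return List of class \code{rhs_pipeline_config}.
#' @details Threshold defaults: \code{cluster_threshold = 0.90},
#'   \code{pair_id = 0.70}, \code{pair_cov = 0.70},
#'   \code{presence_id = 0.50}, \code{presence_cov = 0.50},
#'   \code{domain_min_nt = 40}, \code{stringent_min_nt = 200},
#'   \code{locus_gap_nt = 5000}, \code{immunity_distance_nt = 200},
#'   \code{t6ss_min_frac = 0.8}, \code{min_orf_aa = 60},
#'   \code{rhs_min_aa = 100}.
#' @export
pipeline_config <- function(seed = 1, simulate = list(), input_dir = NULL,
                            metadata = NULL, thresholds = list(),
                            domain_mode = c("default", "stringent")) {
  domain_mode <- match.arg(domain_mode)
  th <- list(cluster_threshold = 0.90, pair_id = 0.70, pair_cov = 0.70,
             presence_id = 0.50, presence_cov = 0.50,
             domain_min_nt = 40, stringent_min_nt = 200,
             locus_gap_nt = 5000, immunity_distance_nt = 200,
             t6ss_min_frac = 0.8, min_orf_aa = 60, rhs_min_aa = 100)
  th[names(thresholds)] <- thresholds
  frac <- unlist(th[c("cluster_threshold", "pair_id", "pair_cov",
                      "presence_id", "presence_cov", "t6ss_min_frac")])
  stopifnot(all(frac >= 0 & frac <= 1),
            th$domain_min_nt > 0, th$stringent_min_nt > 0,
            th$locus_gap_nt > 0, th$immunity_distance_nt > 0)
  structure(list(seed = as.integer(seed), simulate = simulate,
                 input_dir = input_dir, metadata = metadata,
                 thresholds = th, domain_mode = domain_mode),
            class = "rhs_pipeline_config")
}

#' @rdname pipeline_config
#' @param config Configuration object to write.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[c("seed", "simulate", "input_dir", "metadata",
                               "thresholds", "domain_mode")])
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate (or ingest) genomes; detect ORFs
#' and Rhs genes; split cores from C-terminal toxin domains; pair toxins
#' with immunity genes and find orphans; cluster domains and build the
#' co-occurrence network; screen genomes against the reference strain's
#' T6SS genes and toxin/immunity pairs; compute Rhs-count group statistics
#' and (in simulation mode) tree congruence; write the report. All outputs
#' are plain TSV/JSON/FASTA/GFF3/GraphML files in \code{outdir}; re-running
#' with the same configuration reproduces them byte-identically.
#'
#' @param config \code{\link{pipeline_config}}.
#' @param outdir Output directory.
#' @param reference_strain Strain whose genes serve as screening queries
#'   (default: first strain).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, outdir, reference_strain = NULL) {
  stopifnot(inherits(config, "rhs_pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  log_msg <- function(stage, ...) {
    message(sprintf("[rhscan:%s] %s", stage, paste0(...)))
  }

  ## --- stage: simulate / ingest ---
  sim <- NULL
  if (is.null(config$input_dir)) {
    log_msg("simulate", "generating synthetic strains")
    sim_cfg <- do.call(simulation_config,
                       c(config$simulate,
                         if (is.null(config$simulate$seed))
                           list(seed = config$seed)))
    sim <- simulate_strains(sim_cfg)
    write_truth(sim, file.path(outdir, "truth"))
    genomes <- lapply(names(sim$genomes), function(st) sim$genomes[st])
    names(genomes) <- names(sim$genomes)
    strain_table <- sim$truth$metadata
  } else {
    log_msg("ingest", "reading genomes from ", config$input_dir)
    genomes <- read_genomes(config$input_dir)
    if (length(genomes) == 0L) stop("run_pipeline: no genome FASTA files")
    strain_table <- if (!is.null(config$metadata)) {
      .read_tsv(config$metadata)
    } else {
      data.frame(strain_id = names(genomes), species = "unknown",
                 host = "unknown", region = "unknown",
                 stringsAsFactors = FALSE)
    }
  }
  strains <- names(genomes)
  if (is.null(reference_strain)) reference_strain <- strains[1]

  ## --- stage: genes ---
  log_msg("genes", "calling ORFs and Rhs genes in ", length(strains),
          " genomes")
  orfs <- list(); rhs <- list(); proteomes <- list()
  for (st in strains) {
    o <- do.call(rbind, lapply(seq_along(genomes[[st]]), function(i) {
      find_orfs(as.character(genomes[[st]][[i]]),
                min_aa_len = th$min_orf_aa,
                contig_id = names(genomes[[st]])[i])
    }))
    orfs[[st]] <- o
    proteomes[[st]] <- Biostrings::AAStringSet(
      stats::setNames(o$aa, o$orf_id))
    g <- call_rhs_genes(genomes[[st]], min_aa_len = th$rhs_min_aa,
                        mode = config$domain_mode)
    g <- classify_architecture(assemble_loci(g, th$locus_gap_nt))
    g$strain <- st
    rhs[[st]] <- g
  }
  gene_table <- do.call(rbind, rhs)
  .write_tsv(gene_table[, setdiff(names(gene_table), c("nt", "aa"))],
             file.path(outdir, "rhs_genes.tsv"))
  export_gene_gff3(gene_table, file.path(outdir, "rhs_genes.gff3"))

  ## --- stage: domains ---
  log_msg("domains", "extracting C-terminal toxin domains")
  dom <- extract_cterm(gene_table, mode = config$domain_mode,
                       min_nt = if (config$domain_mode == "default")
                         th$domain_min_nt else th$stringent_min_nt)
  dom$strain <- gene_table$strain
  .write_tsv(dom[, c("gene_id", "strain", "start_aa", "length_nt",
                     "status")],
             file.path(outdir, "domains.tsv"))
  ok_dom <- dom[dom$status == "ok", ]
  if (nrow(ok_dom)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(ok_dom$nt, ok_dom$gene_id)),
      file.path(outdir, "domains_nt.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(stats::setNames(ok_dom$aa, ok_dom$gene_id)),
      file.path(outdir, "domains_aa.fasta"))
  }

  ## --- stage: immunity ---
  log_msg("immunity", "pairing toxins with downstream immunity genes")
  pairs <- do.call(rbind, lapply(strains, function(st) {
    p <- pair_immunity(rhs[[st]], orfs[[st]],
                       max_intergenic_nt = th$immunity_distance_nt)
    if (nrow(p)) p$strain <- st else p$strain <- character(0)
    p
  }))
  .write_tsv(pairs[, c("toxin_id", "strain", "immunity_id", "distance_nt",
                       "architecture")],
             file.path(outdir, "immunity_pairs.tsv"))
  ref_imm <- pairs[pairs$strain == reference_strain &
                     !is.na(pairs$immunity_id), ]
  orphans <- NULL
  if (nrow(ref_imm)) {
    ref_set <- Biostrings::AAStringSet(
      stats::setNames(ref_imm$immunity_aa, ref_imm$immunity_id))
    orphans <- do.call(rbind, lapply(strains, function(st) {
      o <- find_orphan_immunity(orfs[[st]], ref_set, rhs[[st]],
                                genomes[[st]],
                                id_threshold = th$pair_id,
                                cov_threshold = th$pair_cov,
                                max_intergenic_nt = th$immunity_distance_nt)
      if (nrow(o)) o$strain <- st else o$strain <- character(0)
      o
    }))
    .write_tsv(orphans, file.path(outdir, "orphan_immunity.tsv"))
  }

  ## --- stage: clusters ---
  log_msg("cluster", "clustering ", nrow(ok_dom), " toxin domains at ",
          th$cluster_threshold)
  clustering <- greedy_cluster(
    stats::setNames(ok_dom$nt, ok_dom$gene_id),
    threshold = th$cluster_threshold)
  .write_tsv(clustering, file.path(outdir, "clusters.tsv"))
  reps <- clustering[clustering$is_representative, ]
  if (nrow(reps)) {
    rep_nt <- ok_dom$nt[match(reps$representative_id, ok_dom$gene_id)]
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(rep_nt, reps$cluster_id)),
      file.path(outdir, "cluster_representatives.fasta"))
  }
  net <- build_network(clustering,
                       stats::setNames(ok_dom$strain, ok_dom$gene_id),
                       strain_table)
  igraph::write_graph(net, file.path(outdir, "network.graphml"),
                      format = "graphml")
  el <- igraph::as_data_frame(net, what = "edges")
  .write_tsv(el, file.path(outdir, "network_edges.tsv"))
  sharing <- sharing_stats(net)
  .write_tsv(sharing$per_cluster, file.path(outdir, "sharing.tsv"))

  ## --- stage: screen ---
  log_msg("screen", "screening genomes against ", reference_strain,
          " queries")
  ref_rhs <- rhs[[reference_strain]]
  ref_orfs <- orfs[[reference_strain]]
  queries <- NULL; status <- NULL; cooc <- NULL
  t6ss_queries <- .t6ss_reference_queries(sim, ref_orfs, reference_strain)
  if (!is.null(t6ss_queries)) {
    pm <- presence_matrix(t6ss_queries$set, proteomes,
                          id_min = th$presence_id,
                          cov_min = th$presence_cov)
    .write_tsv(pm, file.path(outdir, "presence.tsv"))
    status <- t6ss_status(pm, t6ss_queries$systems,
                          min_frac = th$t6ss_min_frac)
    .write_tsv(status, file.path(outdir, "t6ss_status.tsv"))
  }
  ref_pairs <- .reference_pairs(ref_rhs, dom, pairs, reference_strain)
  if (nrow(ref_pairs)) {
    cooc <- toxin_immunity_cooccurrence(ref_pairs, proteomes,
                                        id_min = th$pair_id,
                                        cov_min = th$pair_cov)
    .write_tsv(cooc, file.path(outdir, "cooccurrence.tsv"))
  }

  ## --- stage: stats ---
  log_msg("stats", "group statistics and congruence")
  stats_out <- list()
  if (!is.null(status)) {
    counts <- rhs_count_by_t6ss_group(gene_table, status, strains)
    .write_tsv(counts, file.path(outdir, "rhs_counts.tsv"))
    if (length(unique(counts$group)) >= 2) {
      at <- anova_tukey(counts$n_rhs, counts$group)
      stats_out$anova <- list(F = at$F, p = at$p)
      stats_out$tukey <- at$tukey
    }
  }
  if (!is.null(sim)) {
    ms <- sim$truth$marker_seqs
    hk_tree <- nj_tree(pdistance_matrix(ms$housekeeping))
    t1 <- ms$t6ss1[!is.na(ms$t6ss1)]
    if (length(t1) >= 3) {
      t1_tree <- nj_tree(pdistance_matrix(t1))
      if (length(t1) == length(ms$housekeeping)) {
        stats_out$rf_t6ss1_vs_housekeeping <-
          rf_distance(t1_tree, hk_tree)
      }
      ape::write.tree(t1_tree, file.path(outdir, "t6ss1_nj.newick"))
    }
    ape::write.tree(hk_tree, file.path(outdir, "housekeeping_nj.newick"))
  }

  ## --- stage: report ---
  report <- list(
    n_strains = length(strains),
    n_rhs_genes = nrow(gene_table),
    rhs_per_strain = as.list(table(gene_table$strain)),
    n_domains = nrow(ok_dom),
    n_clusters = sum(clustering$is_representative),
    n_orphan_immunity = if (is.null(orphans)) 0L else nrow(orphans),
    cooccurrence_violations = if (is.null(cooc)) NA_integer_ else
      sum(cooc$violation),
    sharing = as.list(sharing$summary),
    t6ss_status = if (is.null(status)) NULL else status,
    stats = stats_out)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("rhscan")),
                   seed = config$seed,
                   thresholds = th,
                   domain_mode = config$domain_mode,
                   mode = if (is.null(config$input_dir)) "simulate"
                          else "ingest")
  cfg_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("report", "done: ", outdir)
  invisible(list(genomes = genomes, sim = sim, genes = gene_table,
                 domains = dom, pairs = pairs, orphans = orphans,
                 clustering = clustering, network = net, sharing = sharing,
                 status = status, cooccurrence = cooc, report = report))
}

## reference T6SS queries: in simulation mode the marker genes are known by
## name in the reference strain's ORF set (same coordinates as truth)
.t6ss_reference_queries <- function(sim, ref_orfs, reference_strain) {
  if (is.null(sim)) return(NULL)
  tg <- sim$truth$genes
  tg <- tg[tg$strain == reference_strain &
             tg$class %in% c("t6ss1", "t6ss23"), , drop = FALSE]
  if (nrow(tg) == 0L) return(NULL)
  key <- paste(ref_orfs$contig, ref_orfs$start, ref_orfs$end)
  idx <- match(paste(tg$contig, tg$start, tg$end), key)
  ok <- !is.na(idx)
  if (!any(ok)) return(NULL)
  qs <- stats::setNames(ref_orfs$aa[idx[ok]],
                        sub("^.*?_(t2_)?tss", "\\1tss", tg$gene_id[ok]))
  list(set = Biostrings::AAStringSet(qs),
       systems = list(
         t6ss1 = grep("^tss", names(qs), value = TRUE),
         t6ss23 = grep("^t2_", names(qs), value = TRUE)))
}

## reference toxin/immunity pairs for the co-occurrence screen; toxinless
## genes (no domain, no cognate immunity) are excluded by construction
.reference_pairs <- function(ref_rhs, dom, pairs, reference_strain) {
  dom_ref <- dom[dom$strain == reference_strain & dom$status == "ok", ]
  p_ref <- pairs[pairs$strain == reference_strain, ]
  m <- merge(dom_ref[, c("gene_id", "aa")],
             p_ref[!is.na(p_ref$immunity_id),
                   c("toxin_id", "immunity_aa")],
             by.x = "gene_id", by.y = "toxin_id")
  data.frame(pair_id = m$gene_id, toxin_aa = m$aa,
             immunity_aa = m$immunity_aa, stringsAsFactors = FALSE)
}
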