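## Truth and genome input/output: FASTA via Biostrings, GFF3 via
## rtracklayer, tables via JSON/TSV. Coordinates are 1-based inclusive
## throughout, matching the GFF3 convention.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read genome FASTA files from a directory
#'
#' One file per strain; every contig name is prefixed with the strain id
#' (file name without extension) unless it already carries it.
#'
#' @param dir Directory containing \code{.fasta}/\code{.fa} files.
#' @return Named list of \code{DNAStringSet}, one per strain.
#' @export
read_genomes <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  out <- lapply(files, Biostrings::readDNAStringSet)
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  for (i in seq_along(out)) {
    names(out[[i]]) <- sub("\\s.*$", "", names(out[[i]]))
  }
  out
}

#' Write a simulation (genomes plus ground truth) to disk
#'
#' Emits per-strain genome FASTA files, the truth annotation as GFF3
#' (1-based, inclusive), the truth tables and configuration as JSON, the
#' strain tree as newick and the strain metadata as TSV. The on-disk form
#' round-trips through \code{\link{read_truth}}.
#'
#' @param sim \code{rhs_simulation} from \code{\link{simulate_strains}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_truth <- function(sim, dir) {
  stopifnot(inherits(sim, "rhs_simulation"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("write_truth: cannot write to ", dir)
  }
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, showWarnings = FALSE)
  for (st in names(sim$genomes)) {
    Biostrings::writeXStringSet(sim$genomes[st],
                                file.path(gdir, paste0(st, ".fasta")))
  }
  genes <- sim$truth$genes
  if (is.null(genes)) genes <- .empty_truth_genes()
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(genes)) genes$contig else character(0),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = rep("gene", nrow(genes)),
    ID = genes$gene_id, class = genes$class, locus_id = genes$locus_id,
    position_in_locus = genes$position_in_locus,
    prototype = genes$prototype, architecture = genes$architecture,
    pseudogene = genes$pseudogene, orphan_immunity = genes$orphan_immunity)
  .export_gff3(gr, file.path(dir, "truth.gff3"))
  writeLines(sim$truth$newick, file.path(dir, "tree.newick"))
  .write_tsv(sim$truth$metadata, file.path(dir, "metadata.tsv"))
  cfg <- unclass(sim$config)
  jsonlite::write_json(
    list(config = cfg,
         genes = genes,
         t6ss = sim$truth$t6ss,
         metadata = sim$truth$metadata,
         pool = lapply(sim$truth$pool, as.list),
         marker_seqs = lapply(sim$truth$marker_seqs, as.list),
         events = sim$truth$events,
         t6ss_hgt_pair = sim$truth$t6ss_hgt_pair,
         newick = sim$truth$newick),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(dir)
}

.empty_truth_genes <- function() {
  data.frame(strain = character(0), contig = character(0),
             gene_id = character(0), class = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             locus_id = character(0), position_in_locus = integer(0),
             prototype = character(0), architecture = character(0),
             pseudogene = logical(0), orphan_immunity = logical(0),
             short_control = logical(0), cognate = character(0),
             lesion_codon = integer(0), length_nt = integer(0), core_start_aa = integer(0),
             core_end_aa = integer(0), motif_end_aa = integer(0),
             n_repeats = integer(0), domain_start = integer(0),
             domain_end = integer(0), stringsAsFactors = FALSE)
}

#' Read a simulation back from disk
#'
#' Inverse of \code{\link{write_truth}}.
#'
#' @param dir Directory written by \code{\link{write_truth}}.
#' @return \code{rhs_simulation} object.
#' @export
read_truth <- function(dir) {
  j <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                          simplifyDataFrame = TRUE)
  genes <- j$genes
  if (length(genes) == 0L || nrow(as.data.frame(genes)) == 0L) {
    genes <- .empty_truth_genes()
  } else {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    tmpl <- .empty_truth_genes()
    for (col in names(tmpl)) {
      genes[[col]] <- methods::as(genes[[col]], class(tmpl[[col]]))
    }
    genes <- genes[, names(tmpl)]
  }
  glist <- read_genomes(file.path(dir, "genomes"))
  genomes <- Biostrings::DNAStringSet(unlist(lapply(glist, as.character)))
  if (length(glist)) names(genomes) <- names(glist)
  cfg <- j$config
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "rhs_sim_config"
  newick <- j$newick
  tree <- if (grepl("\\(", newick)) ape::read.tree(text = newick) else NULL
  structure(list(
    genomes = genomes,
    truth = list(genes = genes, tree = tree, newick = newick,
                 metadata = as.data.frame(j$metadata,
                                          stringsAsFactors = FALSE),
                 t6ss = as.data.frame(j$t6ss, stringsAsFactors = FALSE),
                 pool = list(toxin = unlist(j$pool$toxin),
                             immunity = unlist(j$pool$immunity)),
                 marker_seqs = lapply(j$marker_seqs, unlist),
                 events = j$events,
                 t6ss_hgt_pair = j$t6ss_hgt_pair),
    config = cfg), class = "rhs_simulation")
}

#' Export a called gene table as GFF3
#'
#' @param genes Classified Rhs gene table.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
export_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(genes)) genes$contig else character(0),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = rep("gene", nrow(genes)),
    ID = genes$gene_id,
    locus_id = genes$locus_id,
    position_in_locus = genes$position_in_locus,
    architecture = genes$architecture,
    has_paar = genes$has_paar,
    n_repeats = genes$n_repeats,
    pseudogene = genes$pseudogene)
  .export_gff3(gr, path)
  invisible(path)
}

## empty GRanges trip rtracklayer's GFF writer; emit a bare header instead
.export_gff3 <- function(gr, path) {
  if (length(gr) == 0L) {
    writeLines("##gff-version 3", path)
  } else {
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}
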