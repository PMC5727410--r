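## Synthetic strain genomes under the C-terminal displacement model.
##
## Design notes that matter for downstream exactness:
##  * Intergenic sequence is drawn from {A,C,T}. Without G there are no
##    start codons (ATG/GTG/TTG) outside genes on the forward strand, so ORF
##    boundaries are unambiguous.
##  * Every gene is preceded by the pad TAAATAAATAA, which places an
##    in-frame stop in all three frames immediately upstream, so called ORFs
##    begin exactly at the planted start codon.
##  * Mutations never touch start/stop codons or the conserved residues of
##    the PAAR, YD-repeat and DPXG(18)DPXG motifs, and never create stop
##    codons, so detection ground truth stays exact.

.BASES <- c("A", "C", "G", "T")
.PAD <- "TAAATAAATAA"

.sense_codons <- local({
  v <- NULL
  function() {
    if (is.null(v)) {
      gc <- Biostrings::GENETIC_CODE
      v <<- names(gc)[gc != "*"]
    }
    v
  }
})

## one fixed codon per amino acid, for motif-critical (frozen) residues
.AA2CODON <- c(G = "GGT", Y = "TAT", D = "GAT", R = "CGT", L = "CTG",
               P = "CCG", A = "GCT", S = "TCT", M = "ATG")

.rand_codons <- function(n) {
  paste(sample(.sense_codons(), n, replace = TRUE), collapse = "")
}

## edge indices of a phylo tree in parent-before-child order
.preorder_edges <- function(tree) {
  n_edge <- nrow(tree$edge)
  root <- length(tree$tip.label) + 1L
  known <- root
  ord <- integer(0)
  remaining <- seq_len(n_edge)
  while (length(remaining)) {
    ready <- remaining[tree$edge[remaining, 1] %in% known]
    if (!length(ready)) stop("internal: disconnected tree")
    ord <- c(ord, ready)
    known <- c(known, tree$edge[ready, 2])
    remaining <- setdiff(remaining, ready)
  }
  ord
}

## cognate immunity prototype of a toxin prototype
.imm_of <- function(p) sub("^tox", "imm", p)

## integer draw(s) from [a, b], safe for a == b
.rint <- function(a, b, n = 1) {
  if (a == b) rep(as.integer(a), n) else sample(seq(a, b), n, replace = TRUE)
}

.gfree <- function(n) {
  paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
}

#' Configuration for the synthetic-genome generator
#'
#' Defaults describe the regime the package's validation runs in: 20 strains
#' on a random bifurcating tree, a pool of 50 toxin-domain prototypes whose
#' pairwise identity is kept below \code{cluster_threshold - margin} so that
#' ground-truth clusters are separable, and a per-branch substitution rate
#' low enough that copies of one prototype stay within a few percent of each
#' other.
#'
#' @param n_strains Number of strains (tips).
#' @param tree_mode \code{"random_bifurcating"} or \code{"fixed_newick"}.
#' @param fixed_newick Newick string when \code{tree_mode == "fixed_newick"}.
#' @param pool_size Number of distinct toxin-domain prototypes.
#' @param domain_length_range Toxin-domain length range in nt (rounded to
#'   codons).
#' @param core_length_range Lead-gene core length range in residues (gene
#'   start through end of the DPXG motif).
#' @param repeats_per_core YD-repeat copies per core.
#' @param per_branch_substitution_rate Substitution probability per site per
#'   tree branch.
#' @param p_pseudogenize Probability a toxin gene acquires a nonsense lesion.
#' @param p_orphan_immunity Probability an orphan slot loses its toxin but
#'   keeps the immunity gene.
#' @param p_orphan_pseudogenize Probability an orphaned immunity gene itself
#'   carries a nonsense lesion.
#' @param p_hgt Probability per toxin slot per strain of importing a
#'   different pool domain (with its cognate immunity gene).
#' @param loci_per_strain_range,orphans_per_locus_range Locus architecture.
#' @param p_toxinless Probability a locus ends in a toxinless
#'   (core-only) gene.
#' @param n_decoy_orfs Decoy ORFs per strain (no Rhs features).
#' @param short_domain_controls Number of strains that receive one extra
#'   orphan whose domain is shorter than the 40-nt filter.
#' @param immunity_length_range Immunity gene length range (nt).
#' @param n_housekeeping,housekeeping_length_range Housekeeping marker genes
#'   used for the reference phylogeny.
#' @param t6ss_gene_length_range Length range of T6SS core genes (nt).
#' @param t6ss1_absent,t6ss23_absent Strain indices lacking each system.
#' @param loci_when_no_t6ss1_range Rhs locus count for strains without the
#'   Rhs-associated system.
#' @param t6ss_hgt \code{NULL}, \code{"auto"} (copy the T6SS of the most
#'   distant donor into a recipient) or \code{c(donor, recipient)} indices.
#' @param spacer_nt Intergenic distance between a toxin's stop and its
#'   immunity gene's start.
#' @param gene_gap_range,locus_gap_range Intergenic distances within and
#'   between loci (nt).
#' @param randomize_strand Flip whole Rhs loci onto the reverse strand at
#'   random.
#' @param cluster_threshold,separability_margin Pool separability regime.
#' @param seed Random seed; every random choice derives from it.
#' @return Object of class \code{rhs_sim_config} (a validated list).
#' @export
simulation_config <- function(n_strains = 20,
                              tree_mode = c("random_bifurcating",
                                            "fixed_newick"),
                              fixed_newick = NULL,
                              pool_size = 50,
                              domain_length_range = c(120, 900),
                              core_length_range = c(180, 240),
                              repeats_per_core = 6,
                              per_branch_substitution_rate = 0.002,
                              p_pseudogenize = 0.05,
                              p_orphan_immunity = 0.08,
                              p_orphan_pseudogenize = 0.3,
                              p_hgt = 0.05,
                              loci_per_strain_range = c(3, 3),
                              orphans_per_locus_range = c(3, 5),
                              p_toxinless = 0.2,
                              n_decoy_orfs = 30,
                              short_domain_controls = 2,
                              immunity_length_range = c(300, 450),
                              n_housekeeping = 8,
                              housekeeping_length_range = c(600, 1200),
                              t6ss_gene_length_range = c(450, 1200),
                              t6ss1_absent = integer(0),
                              t6ss23_absent = integer(0),
                              loci_when_no_t6ss1_range = c(0, 1),
                              t6ss_hgt = NULL,
                              spacer_nt = 30,
                              gene_gap_range = c(80, 200),
                              locus_gap_range = c(6000, 8000),
                              randomize_strand = FALSE,
                              cluster_threshold = 0.90,
                              separability_margin = 0.05,
                              seed = 1) {
  tree_mode <- match.arg(tree_mode)
  cfg <- as.list(environment())
  stopifnot(n_strains >= 1, pool_size >= 1,
            domain_length_range[1] >= 15,
            diff(domain_length_range) >= 0,
            repeats_per_core >= 1,
            per_branch_substitution_rate >= 0,
            per_branch_substitution_rate < 1,
            all(c(p_pseudogenize, p_orphan_immunity, p_hgt,
                  p_toxinless) >= 0),
            all(c(p_pseudogenize, p_orphan_immunity, p_hgt,
                  p_toxinless) <= 1),
            loci_per_strain_range[1] >= 0,
            separability_margin >= 0.05,
            spacer_nt > nchar(.PAD))
  if (tree_mode == "fixed_newick" && is.null(fixed_newick)) {
    stop("simulation_config: fixed_newick tree mode needs a newick string")
  }
  ## fixed residues of a lead gene's core, excluding repeats
  fixed_aa <- 1 + 10 + 30 + 26
  if (core_length_range[1] < fixed_aa + 16 * repeats_per_core + 5) {
    stop("simulation_config: core_length_range too short for ",
         repeats_per_core, " repeats")
  }
  class(cfg) <- "rhs_sim_config"
  cfg
}

## ---- toxin / immunity prototype pools ------------------------------------

.make_pool <- function(config) {
  limit <- config$cluster_threshold - config$separability_margin
  n <- config$pool_size
  lens <- 3L * (.rint(config$domain_length_range[1],
                     config$domain_length_range[2], n) %/% 3L)
  pool <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in 1:25) {
      cand <- .clean_domain(lens[i] %/% 3L)
      if (i == 1L ||
          all(identity_to_set(Biostrings::DNAStringSet(pool[seq_len(i - 1)]),
                              cand) < limit)) {
        pool[i] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("generate_toxin_pool: cannot draw ", n,
           " prototypes separable below ", limit,
           " identity in the configured length range")
    }
  }
  names(pool) <- sprintf("tox%03d", seq_len(n))
  pool
}

## Random domain free of Rhs signature artefacts: no DPXG window inside the
## domain or spanning the junction with the upstream motif (the DPAG prefix
## stands in for the motif's final tetrad), no PAAR motif, no YD repeat.
## Such accidents would otherwise shift the detected core/toxin boundary.
.clean_domain <- function(n_codons) {
  for (attempt in 1:40) {
    nt <- .rand_codons(n_codons)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    if (is.null(locate_dpxg(paste0("DPAG", aa), mode = "default")) &&
        is.null(detect_paar(aa)) &&
        is.null(scan_rhs_core(aa, min_repeats = 1))) {
      return(nt)
    }
  }
  stop("internal: could not draw a motif-free domain")
}

#' Generate the toxin-domain prototype pool
#'
#' Draws \code{pool_size} random coding nucleotide domains whose pairwise
#' identities all fall below \code{cluster_threshold - separability_margin},
#' verified by alignment and redrawn on violation (bounded attempts), so the
#' planted cluster structure is recoverable by construction. Deterministic
#' for a given seed.
#'
#' @param config \code{\link{simulation_config}}.
#' @return Named character vector of prototype nucleotide sequences.
#' @export
generate_toxin_pool <- function(config) {
  stopifnot(inherits(config, "rhs_sim_config"))
  set.seed(config$seed)
  .make_pool(config)
}

.make_immunity_pool <- function(config) {
  n <- config$pool_size
  lens <- 3L * (.rint(config$immunity_length_range[1],
                     config$immunity_length_range[2], n) %/% 3L)
  pool <- vapply(lens, function(L) .rand_codons(L %/% 3L - 2L), character(1))
  pool <- paste0("ATG", pool, "TAA")
  names(pool) <- sprintf("imm%03d", seq_len(n))
  pool
}

## ---- gene construction ----------------------------------------------------

.freeze <- function(n) rep(FALSE, n)

.motif_codons <- function() {
  x1 <- sample(.sense_codons(), 1)
  x2 <- sample(.sense_codons(), 1)
  nt <- paste0(.AA2CODON[["D"]], .AA2CODON[["P"]], x1, .AA2CODON[["G"]],
               .rand_codons(18),
               .AA2CODON[["D"]], .AA2CODON[["P"]], x2, .AA2CODON[["G"]])
  frozen <- rep(FALSE, 26 * 3)
  conserved <- c(1, 2, 4, 23, 24, 26)  # codon indices of D,P,G,D,P,G
  for (ci in conserved) frozen[(3 * (ci - 1) + 1):(3 * ci)] <- TRUE
  list(nt = nt, frozen = frozen)
}

.repeat_block <- function(k) {
  unit_aa <- strsplit("..G..Y.YD..GRL..", "")[[1]]
  nts <- character(0); frz <- logical(0)
  for (r in seq_len(k)) {
    for (p in seq_along(unit_aa)) {
      if (unit_aa[p] == ".") {
        nts <- c(nts, sample(.sense_codons(), 1))
        frz <- c(frz, rep(FALSE, 3))
      } else {
        nts <- c(nts, .AA2CODON[[unit_aa[p]]])
        frz <- c(frz, rep(TRUE, 3))
      }
    }
  }
  list(nt = paste(nts, collapse = ""), frozen = frz)
}

.paar_block <- function() {
  nt <- paste0(.rand_codons(3),
               .AA2CODON[["P"]], .AA2CODON[["A"]], .AA2CODON[["A"]],
               .AA2CODON[["R"]], .AA2CODON[["S"]],
               .rand_codons(2))
  frozen <- c(rep(FALSE, 9), rep(TRUE, 15), rep(FALSE, 6))
  list(nt = nt, frozen = frozen)
}

## Assemble a toxin gene. kind: "lead" (PAAR + long N-terminus), "orphan"
## (short N-terminus), "toxinless" (no motif, no domain).
## Verified post-construction: the translated protein must yield exactly the
## intended PAAR/repeat/motif calls; free parts are redrawn on failure.
.build_toxin_gene <- function(kind, domain_nt, config) {
  k <- config$repeats_per_core
  for (attempt in 1:25) {
    parts_nt <- "ATG"
    parts_frz <- rep(TRUE, 3)
    if (kind == "lead") {
      pb <- .paar_block()
      core_len <- .rint(config$core_length_range[1],
                        config$core_length_range[2])
      filler_aa <- core_len - (1 + 10 + 16 * k + 30 + 26)
      parts_nt <- c(parts_nt, pb$nt, .rand_codons(filler_aa))
      parts_frz <- c(parts_frz, pb$frozen, .freeze(3 * filler_aa))
    } else {
      parts_nt <- c(parts_nt, .rand_codons(15))
      parts_frz <- c(parts_frz, .freeze(45))
    }
    rb <- .repeat_block(k)
    parts_nt <- c(parts_nt, rb$nt)
    parts_frz <- c(parts_frz, rb$frozen)
    n_before_linker <- sum(nchar(parts_nt)) %/% 3L
    linker_codons <- 30L
    parts_nt <- c(parts_nt, .rand_codons(linker_codons))
    parts_frz <- c(parts_frz, .freeze(3 * linker_codons))
    if (kind == "toxinless") {
      parts_nt <- c(parts_nt, .rand_codons(40), "TAA")
      parts_frz <- c(parts_frz, .freeze(120), rep(TRUE, 3))
      motif_end_aa <- NA_integer_
    } else {
      mb <- .motif_codons()
      parts_nt <- c(parts_nt, mb$nt, domain_nt, "TAA")
      parts_frz <- c(parts_frz, mb$frozen, .freeze(nchar(domain_nt)),
                     rep(TRUE, 3))
      motif_end_aa <- n_before_linker + linker_codons + 26L
    }
    nt <- paste(parts_nt, collapse = "")
    frozen <- parts_frz
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(nt, 1, nchar(nt) - 3))))
    if (grepl("\\*", aa)) next
    core <- scan_rhs_core(aa, min_repeats = 4)
    if (is.null(core) || core$n_repeats != k) next
    paar_ok <- if (kind == "lead") !is.null(detect_paar(aa))
               else is.null(detect_paar(aa))
    if (!paar_ok) next
    motif <- locate_dpxg(aa, mode = "default")
    if (kind == "toxinless") {
      if (!is.null(motif)) next
    } else {
      if (is.null(motif) || motif$end != motif_end_aa) next
    }
    return(list(nt = nt, frozen = frozen,
                meta = list(kind = kind,
                            core_start_aa = core$start,
                            core_end_aa = if (kind == "toxinless")
                              nchar(aa) else motif_end_aa,
                            n_repeats = k,
                            motif_end_aa = motif_end_aa,
                            linker_codon_range = c(n_before_linker + 1L,
                                                   n_before_linker +
                                                     linker_codons),
                            domain_nt_start = if (kind == "toxinless")
                              NA_integer_ else 3L * motif_end_aa + 1L,
                            domain_len_nt = if (kind == "toxinless") 0L
                              else nchar(domain_nt))))
  }
  stop("internal: toxin gene construction kept failing verification")
}

.build_plain_gene <- function(len_nt) {
  n_codons <- len_nt %/% 3L
  nt <- paste0("ATG", .rand_codons(n_codons - 2L), "TAA")
  frozen <- c(rep(TRUE, 3), .freeze(nchar(nt) - 6L), rep(TRUE, 3))
  list(nt = nt, frozen = frozen, meta = list())
}

.build_decoy <- function(config) {
  for (attempt in 1:25) {
    g <- .build_plain_gene(3L * .rint(80, 250))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(g$nt, 1, nchar(g$nt) - 3))))
    if (is.null(scan_rhs_core(aa, min_repeats = 1)) &&
        is.null(detect_paar(aa)) &&
        is.null(locate_dpxg(aa))) {
      return(g)
    }
  }
  stop("internal: decoy construction kept failing verification")
}

## ---- mutation along the tree ---------------------------------------------

.mutate_gene <- function(gene, rate) {
  if (rate <= 0) return(gene)
  L <- nchar(gene$nt)
  hit <- which(stats::runif(L) < rate)
  hit <- hit[!gene$frozen[hit]]
  if (length(hit) == 0L) return(gene)
  chars <- strsplit(gene$nt, "")[[1]]
  for (p in hit) {
    cstart <- p - ((p - 1L) %% 3L)
    for (b in sample(setdiff(.BASES, chars[p]))) {
      old <- chars[p]
      chars[p] <- b
      codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
      if (codon %in% .STOPS) chars[p] <- old else break
    }
  }
  gene$nt <- paste(chars, collapse = "")
  gene
}

.mutate_genes <- function(genes, rate) lapply(genes, .mutate_gene, rate)

## Replace a single sense codon with a stop reachable by one substitution.
## Returns NULL when no codon in the range qualifies.
.plant_stop <- function(nt, codon_range) {
  cand <- sample(seq(codon_range[1], codon_range[2]))
  for (ci in cand) {
    codon <- substr(nt, 3L * (ci - 1L) + 1L, 3L * ci)
    opts <- list()
    for (p in 1:3) {
      for (b in setdiff(.BASES, substr(codon, p, p))) {
        alt <- codon
        substr(alt, p, p) <- b
        if (alt %in% .STOPS) opts[[length(opts) + 1L]] <- alt
      }
    }
    if (length(opts)) {
      alt <- opts[[sample.int(length(opts), 1)]]
      substr(nt, 3L * (ci - 1L) + 1L, 3L * ci) <- alt
      return(list(nt = nt, codon = ci))
    }
  }
  NULL
}

## ---- main generator -------------------------------------------------------

#' Simulate strain genomes with full ground truth
#'
#' Builds a root genome layout (housekeeping and T6SS marker genes, Rhs loci
#' with lead-then-orphans architecture, decoy ORFs), evolves the coding
#' sequences along a strain tree at a fixed per-branch substitution rate,
#' and applies tip-level events: horizontal import of pool domains,
#' toxin-loss (orphan immunity) events and pseudogenising nonsense lesions.
#' Everything emitted is recorded in the truth tables, so detection,
#' domain-splitting, pairing, clustering and screening can all be scored
#' against a known answer.
#'
#' @param config \code{\link{simulation_config}}.
#' @return Object of class \code{rhs_simulation}: a list with
#'   \code{genomes} (named \code{DNAStringSet}, one contig per strain),
#'   \code{truth} (gene table, tree, metadata, T6SS table, prototype pools,
#'   per-strain marker sequences, event log) and \code{config}.
#' @export
simulate_strains <- function(config) {
  stopifnot(inherits(config, "rhs_sim_config"))
  if (config$loci_per_strain_range[2] == 0 && config$n_housekeeping == 0) {
    stop("simulate_strains: empty locus configuration")
  }
  set.seed(config$seed)
  n <- config$n_strains
  strains <- sprintf("S%02d", seq_len(n))

  tox_pool <- .make_pool(config)
  imm_pool <- .make_immunity_pool(config)

  ## --- tree ---
  if (n == 1L) {
    tree <- NULL
    newick <- paste0(strains, ";")
  } else if (config$tree_mode == "fixed_newick") {
    tree <- ape::read.tree(text = config$fixed_newick)
    if (length(tree$tip.label) != n) {
      stop("simulate_strains: fixed tree has wrong number of tips")
    }
    tree$tip.label <- strains
    newick <- ape::write.tree(tree)
  } else {
    tree <- ape::rtree(n, tip.label = strains)
    newick <- ape::write.tree(tree)
  }

  ## --- root layout ---
  n_loci_full <- .rint(config$loci_per_strain_range[1],
                       config$loci_per_strain_range[2])
  loci <- lapply(seq_len(max(n_loci_full, 1)), function(l) {
    n_orph <- .rint(config$orphans_per_locus_range[1],
                    config$orphans_per_locus_range[2])
    list(n_orphans = n_orph,
         toxinless = stats::runif(1) < config$p_toxinless,
         prototypes = sample(names(tox_pool), 1 + n_orph, replace = TRUE))
  })
  if (n_loci_full == 0) loci <- list()

  root <- list()
  hk_names <- sprintf("hk%02d", seq_len(config$n_housekeeping))
  for (h in hk_names) {
    root[[h]] <- .build_plain_gene(3L * (.rint(
      config$housekeeping_length_range[1],
      config$housekeeping_length_range[2]) %/% 3L))
    root[[h]]$meta$class <- "housekeeping"
  }
  tss_names <- paste0("tss", LETTERS[1:13])
  for (s in tss_names) {
    root[[s]] <- .build_plain_gene(3L * (.rint(
      config$t6ss_gene_length_range[1],
      config$t6ss_gene_length_range[2]) %/% 3L))
    root[[s]]$meta$class <- "t6ss1"
  }
  for (s in tss_names) {
    id <- paste0("t2_", s)
    root[[id]] <- .build_plain_gene(3L * (sample(seq(
      config$t6ss_gene_length_range[1],
      config$t6ss_gene_length_range[2]), 1) %/% 3L))
    root[[id]]$meta$class <- "t6ss23"
  }
  for (l in seq_along(loci)) {
    lc <- loci[[l]]
    n_slots <- 1 + lc$n_orphans
    for (s in seq_len(n_slots)) {
      kind <- if (s == 1) "lead" else "orphan"
      proto <- lc$prototypes[s]
      gid <- sprintf("L%02d_g%d", l, s)
      g <- .build_toxin_gene(kind, tox_pool[[proto]], config)
      g$meta$class <- paste0("rhs_", kind)
      g$meta$prototype <- proto
      g$meta$locus <- l
      g$meta$slot <- s
      root[[gid]] <- g
      iid <- sprintf("L%02d_i%d", l, s)
      gi <- list(nt = imm_pool[[.imm_of(proto)]],
                 frozen = c(rep(TRUE, 3),
                            .freeze(nchar(imm_pool[[.imm_of(proto)]]) - 6L),
                            rep(TRUE, 3)),
                 meta = list(class = "immunity", prototype = proto,
                             locus = l, slot = s))
      root[[iid]] <- gi
    }
    if (lc$toxinless) {
      gid <- sprintf("L%02d_g%d", l, n_slots + 1)
      g <- .build_toxin_gene("toxinless", NULL, config)
      g$meta$class <- "rhs_toxinless"
      g$meta$locus <- l
      g$meta$slot <- n_slots + 1
      root[[gid]] <- g
    }
  }

  ## --- evolve along the tree ---
  rate <- config$per_branch_substitution_rate
  tip_genes <- vector("list", n)
  names(tip_genes) <- strains
  if (is.null(tree)) {
    tip_genes[[1]] <- root
  } else {
    node_genes <- list()
    node_genes[[as.character(n + 1L)]] <- root   # root node id
    ## preorder traversal so parents are processed before children
    ord <- tree$edge[.preorder_edges(tree), , drop = FALSE]
    for (e in seq_len(nrow(ord))) {
      parent <- as.character(ord[e, 1])
      child <- ord[e, 2]
      mutated <- .mutate_genes(node_genes[[parent]], rate)
      if (child <= n) {
        tip_genes[[tree$tip.label[child]]] <- mutated
      } else {
        node_genes[[as.character(child)]] <- mutated
      }
    }
  }

  ## --- tip-level events ---
  events <- list()
  slot_state <- list()  # per strain: per toxin gene id: status
  for (si in seq_len(n)) {
    st <- strains[si]
    genes <- tip_genes[[st]]
    state <- list()
    for (gid in names(genes)) {
      cls <- genes[[gid]]$meta$class
      if (!cls %in% c("rhs_lead", "rhs_orphan")) next
      state[[gid]] <- list(status = "intact",
                           prototype = genes[[gid]]$meta$prototype)
      ## horizontal import of a different pool domain
      if (stats::runif(1) < config$p_hgt && config$pool_size > 1) {
        new_p <- sample(setdiff(names(tox_pool),
                                genes[[gid]]$meta$prototype), 1)
        g <- genes[[gid]]
        ds <- g$meta$domain_nt_start
        g$nt <- paste0(substr(g$nt, 1, ds - 1L), tox_pool[[new_p]], "TAA")
        g$frozen <- c(g$frozen[seq_len(ds - 1L)],
                      .freeze(nchar(tox_pool[[new_p]])), rep(TRUE, 3))
        g$meta$prototype <- new_p
        g$meta$domain_len_nt <- nchar(tox_pool[[new_p]])
        genes[[gid]] <- g
        iid <- sub("_g", "_i", gid)
        genes[[iid]]$nt <- imm_pool[[.imm_of(new_p)]]
        genes[[iid]]$frozen <- c(rep(TRUE, 3),
                                 .freeze(nchar(imm_pool[[.imm_of(new_p)]]) - 6L),
                                 rep(TRUE, 3))
        genes[[iid]]$meta$prototype <- new_p
        state[[gid]]$prototype <- new_p
        events[[length(events) + 1L]] <- list(type = "hgt", strain = st,
                                              gene = gid, prototype = new_p)
      }
      ## toxin loss leaving an orphan immunity gene
      if (cls == "rhs_orphan" &&
          stats::runif(1) < config$p_orphan_immunity) {
        state[[gid]]$status <- "immunity_only"
        if (stats::runif(1) < config$p_orphan_pseudogenize) {
          iid <- sub("_g", "_i", gid)
          len <- nchar(genes[[iid]]$nt) %/% 3L
          rng <- c(max(2L, floor(0.72 * len)), max(3L, floor(0.85 * len)))
          ps <- .plant_stop(genes[[iid]]$nt, rng)
          if (!is.null(ps)) {
            genes[[iid]]$nt <- ps$nt
            state[[gid]]$imm_lesion <- ps$codon
          }
        }
        events[[length(events) + 1L]] <- list(type = "orphan_immunity",
                                              strain = st, gene = gid)
        next
      }
      ## pseudogenising nonsense lesion in the core/domain linker
      if (stats::runif(1) < config$p_pseudogenize) {
        g <- genes[[gid]]
        ps <- .plant_stop(g$nt, g$meta$linker_codon_range)
        if (!is.null(ps)) {
          genes[[gid]]$nt <- ps$nt
          state[[gid]]$status <- "pseudogene"
          state[[gid]]$lesion <- ps$codon
          events[[length(events) + 1L]] <- list(type = "pseudogenization",
                                                strain = st, gene = gid,
                                                codon = ps$codon)
        }
      }
    }
    tip_genes[[st]] <- genes
    slot_state[[st]] <- state
  }

  ## --- T6SS horizontal transfer (congruence test lever) ---
  hgt_pair <- NULL
  if (!is.null(config$t6ss_hgt) && n >= 4) {
    if (identical(config$t6ss_hgt, "auto")) {
      dm <- ape::cophenetic.phylo(tree)
      ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
      hgt_pair <- c(rownames(dm)[ij[1]], colnames(dm)[ij[2]])
    } else {
      hgt_pair <- strains[config$t6ss_hgt]
    }
    donor <- hgt_pair[1]; recipient <- hgt_pair[2]
    for (s in tss_names) {
      tip_genes[[recipient]][[s]] <- tip_genes[[donor]][[s]]
    }
    events[[length(events) + 1L]] <- list(type = "t6ss_hgt",
                                          donor = donor,
                                          recipient = recipient)
  }

  ## --- assemble genomes and truth ---
  t6ss1_present <- !(seq_len(n) %in% config$t6ss1_absent)
  t6ss23_present <- !(seq_len(n) %in% config$t6ss23_absent)
  out_genomes <- character(n)
  names(out_genomes) <- strains
  truth_rows <- list()
  marker_hk <- marker_t1 <- marker_t2 <- character(0)

  for (si in seq_len(n)) {
    st <- strains[si]
    genes <- tip_genes[[st]]
    state <- slot_state[[st]]
    asmb <- .new_assembly(st)
    asmb <- .asm_filler(asmb, .gfree(300))
    for (h in hk_names) {
      asmb <- .asm_gene(asmb, genes[[h]], id = paste0(st, "_", h),
                        class = "housekeeping")
      asmb <- .asm_filler(asmb, .gfree(.rint(config$gene_gap_range[1],
                                              config$gene_gap_range[2])))
    }
    if (t6ss1_present[si]) {
      for (s in tss_names) {
        asmb <- .asm_gene(asmb, genes[[s]], id = paste0(st, "_", s),
                          class = "t6ss1")
        asmb <- .asm_filler(asmb, .gfree(.rint(
          config$gene_gap_range[1], config$gene_gap_range[2])))
      }
    }
    if (t6ss23_present[si]) {
      for (s in tss_names) {
        id <- paste0("t2_", s)
        asmb <- .asm_gene(asmb, genes[[id]], id = paste0(st, "_", id),
                          class = "t6ss23")
        asmb <- .asm_filler(asmb, .gfree(sample(seq(
          config$gene_gap_range[1], config$gene_gap_range[2]), 1)))
      }
    }
    ## Rhs loci: strains without the Rhs-associated system carry few/none
    n_loci_here <- if (t6ss1_present[si]) length(loci) else
      min(length(loci), .rint(config$loci_when_no_t6ss1_range[1],
                              config$loci_when_no_t6ss1_range[2]))
    short_ctrl_here <- si <= config$short_domain_controls && n_loci_here >= 1
    locus_counter <- 0L
    for (l in seq_len(n_loci_here)) {
      lc <- loci[[l]]
      locus_counter <- locus_counter + 1L
      locus_id <- sprintf("%s_L%02d", st, locus_counter)
      asmb <- .asm_filler(asmb, .gfree(.rint(
        config$locus_gap_range[1], config$locus_gap_range[2])))
      flip <- config$randomize_strand && stats::runif(1) < 0.5
      seg <- .new_assembly(st)
      pos_idx <- 0L
      n_slots <- 1 + lc$n_orphans
      for (s in seq_len(n_slots)) {
        gid <- sprintf("L%02d_g%d", l, s)
        iid <- sprintf("L%02d_i%d", l, s)
        stt <- state[[gid]]
        gap <- .gfree(.rint(config$gene_gap_range[1],
                            config$gene_gap_range[2]))
        if (stt$status != "immunity_only") {
          g <- genes[[gid]]
          arch <- if (stt$status == "pseudogene") "pseudogene"
                  else if (s == 1) "lead" else "orphan"
          seg <- .asm_gene(seg, g, id = paste0(st, "_", gid),
                           class = g$meta$class, locus_id = locus_id,
                           position = pos_idx, prototype = g$meta$prototype,
                           architecture = arch,
                           pseudogene = stt$status == "pseudogene",
                           lesion_codon = if (is.null(stt$lesion))
                             NA_integer_ else stt$lesion,
                           meta = g$meta)
          pos_idx <- pos_idx + 1L
          seg <- .asm_filler(seg, .gfree(config$spacer_nt - nchar(.PAD)))
        }
        ipse <- !is.null(stt$imm_lesion)
        seg <- .asm_gene(seg, genes[[iid]], id = paste0(st, "_", iid),
                         class = "immunity", locus_id = locus_id,
                         prototype = genes[[iid]]$meta$prototype,
                         cognate = if (stt$status == "immunity_only")
                           NA_character_ else paste0(st, "_", gid),
                         orphan_immunity = stt$status == "immunity_only",
                         pseudogene = ipse,
                         lesion_codon = if (ipse) stt$imm_lesion
                           else NA_integer_,
                         architecture = NA_character_)
        seg <- .asm_filler(seg, gap)
      }
      if (lc$toxinless) {
        gid <- sprintf("L%02d_g%d", l, n_slots + 1)
        g <- genes[[gid]]
        seg <- .asm_gene(seg, g, id = paste0(st, "_", gid),
                         class = "rhs_toxinless", locus_id = locus_id,
                         position = pos_idx, architecture = "toxinless",
                         meta = g$meta)
        pos_idx <- pos_idx + 1L
        seg <- .asm_filler(seg, .gfree(60))
      }
      if (short_ctrl_here && l == 1L) {
        dom <- .clean_domain(.rint(9, 12))   # < 40 nt, survives filters
        g <- .build_toxin_gene("orphan", dom, config)
        g$meta$class <- "rhs_orphan"
        seg <- .asm_gene(seg, g, id = sprintf("%s_L%02d_gshort", st, l),
                         class = "rhs_orphan", locus_id = locus_id,
                         position = pos_idx, prototype = "short_control",
                         architecture = "orphan", short_control = TRUE,
                         meta = g$meta)
        pos_idx <- pos_idx + 1L
        ## its immunity gene, so pairing stays complete
        ip <- .build_plain_gene(351)
        seg <- .asm_filler(seg, .gfree(config$spacer_nt - nchar(.PAD)))
        seg <- .asm_gene(seg, ip, id = sprintf("%s_L%02d_ishort", st, l),
                         class = "immunity", locus_id = locus_id,
                         cognate = sprintf("%s_L%02d_gshort", st, l),
                         architecture = NA_character_)
        seg <- .asm_filler(seg, .gfree(60))
      }
      asmb <- .asm_append_segment(asmb, seg, flip = flip)
    }
    for (d in seq_len(config$n_decoy_orfs)) {
      g <- .build_decoy(config)
      asmb <- .asm_gene(asmb, g, id = sprintf("%s_dec%02d", st, d),
                        class = "decoy")
      asmb <- .asm_filler(asmb, .gfree(.rint(60, 150)))
    }
    out_genomes[st] <- .asm_string(asmb)
    truth_rows[[st]] <- .asm_truth(asmb)

    marker_hk[st] <- paste(vapply(hk_names, function(h) genes[[h]]$nt, ""),
                           collapse = "")
    marker_t1[st] <- if (t6ss1_present[si]) {
      paste(vapply(tss_names, function(s) genes[[s]]$nt, ""), collapse = "")
    } else NA_character_
    marker_t2[st] <- if (t6ss23_present[si]) {
      paste(vapply(tss_names, function(s) genes[[paste0("t2_", s)]]$nt, ""),
            collapse = "")
    } else NA_character_
  }

  gene_table <- do.call(rbind, truth_rows)
  rownames(gene_table) <- NULL

  metadata <- .assign_metadata(tree, strains)
  t6ss <- data.frame(strain = strains, t6ss1 = t6ss1_present,
                     t6ss23 = t6ss23_present, stringsAsFactors = FALSE)

  structure(list(
    genomes = Biostrings::DNAStringSet(out_genomes),
    truth = list(genes = gene_table, tree = tree, newick = newick,
                 metadata = metadata, t6ss = t6ss,
                 pool = list(toxin = tox_pool, immunity = imm_pool),
                 marker_seqs = list(housekeeping = marker_hk,
                                    t6ss1 = marker_t1, t6ss23 = marker_t2),
                 events = events, t6ss_hgt_pair = hgt_pair),
    config = config), class = "rhs_simulation")
}

## species from the root bipartition, hosts/regions sampled
.assign_metadata <- function(tree, strains) {
  n <- length(strains)
  if (is.null(tree) || n < 2) {
    species <- rep("SpeciesA", n)
  } else {
    root_children <- tree$edge[tree$edge[, 1] == n + 1L, 2]
    cladeA <- if (root_children[1] <= n) {
      tree$tip.label[root_children[1]]
    } else {
      ape::extract.clade(tree, root_children[1])$tip.label
    }
    species <- ifelse(strains %in% cladeA, "SpeciesA", "SpeciesB")
  }
  data.frame(strain_id = strains,
             species = species,
             host = sample(c("Apis mellifera", "Apis cerana",
                             "Bombus impatiens", "Bombus pensylvanicus"),
                           n, replace = TRUE),
             region = sample(c("NorthAmerica", "SoutheastAsia"), n,
                             replace = TRUE),
             stringsAsFactors = FALSE)
}

## ---- assembly helpers -----------------------------------------------------

.new_assembly <- function(contig) {
  list(contig = contig, chunks = character(0), len = 0L, genes = list())
}

.asm_filler <- function(a, s, pad = FALSE) {
  if (pad) s <- paste0(.PAD, s)
  a$chunks <- c(a$chunks, s)
  a$len <- a$len + nchar(s)
  a
}

.asm_gene <- function(a, gene, id, class, locus_id = NA_character_,
                      position = NA_integer_, prototype = NA_character_,
                      architecture = NA_character_, cognate = NA_character_,
                      pseudogene = FALSE, orphan_immunity = FALSE,
                      short_control = FALSE, lesion_codon = NA_integer_,
                      meta = NULL) {
  a$chunks <- c(a$chunks, .PAD, gene$nt)
  start <- a$len + nchar(.PAD) + 1L
  end <- a$len + nchar(.PAD) + nchar(gene$nt)
  a$len <- end
  m <- if (is.null(meta)) list() else meta
  a$genes[[length(a$genes) + 1L]] <- data.frame(
    strain = a$contig, contig = a$contig, gene_id = id, class = class,
    start = start, end = end, strand = "+",
    locus_id = locus_id, position_in_locus = position,
    prototype = prototype, architecture = architecture,
    pseudogene = pseudogene, orphan_immunity = orphan_immunity,
    short_control = short_control, cognate = cognate,
    lesion_codon = lesion_codon,
    length_nt = nchar(gene$nt),
    core_start_aa = .null2na(m$core_start_aa),
    core_end_aa = .null2na(m$core_end_aa),
    motif_end_aa = .null2na(m$motif_end_aa),
    n_repeats = .null2na(m$n_repeats),
    domain_start = if (!is.null(m$domain_nt_start) &&
                       !is.na(m$domain_nt_start)) {
      start + m$domain_nt_start - 1L
    } else NA_integer_,
    domain_end = if (!is.null(m$domain_nt_start) &&
                     !is.na(m$domain_nt_start)) {
      start + m$domain_nt_start - 1L + m$domain_len_nt - 1L
    } else NA_integer_,
    stringsAsFactors = FALSE)
  a
}

.null2na <- function(x) if (is.null(x)) NA_integer_ else x

## splice a sub-assembly into the parent, optionally reverse-complemented
.asm_append_segment <- function(a, seg, flip = FALSE) {
  s <- .asm_string(seg)
  L <- nchar(s)
  genes <- if (length(seg$genes)) do.call(rbind, seg$genes) else NULL
  if (flip) {
    s <- .revcomp(s)
    if (!is.null(genes)) {
      new_start <- L - genes$end + 1L
      new_end <- L - genes$start + 1L
      ds <- L - genes$domain_end + 1L
      de <- L - genes$domain_start + 1L
      genes$start <- new_start; genes$end <- new_end
      genes$domain_start <- ds; genes$domain_end <- de
      genes$strand <- "-"
    }
  }
  if (!is.null(genes)) {
    genes$start <- genes$start + a$len
    genes$end <- genes$end + a$len
    genes$domain_start <- genes$domain_start + a$len
    genes$domain_end <- genes$domain_end + a$len
    a$genes <- c(a$genes, split(genes, seq_len(nrow(genes))))
  }
  a$chunks <- c(a$chunks, s)
  a$len <- a$len + L
  a
}

.asm_string <- function(a) paste(a$chunks, collapse = "")

.asm_truth <- function(a) {
  if (length(a$genes) == 0L) return(NULL)
  do.call(rbind, a$genes)
}

## ---- paired codon-sequence evolution (for dN/dS calibration) -------------

#' Simulate a pair of diverged coding sequences
#'
#' A random ancestor of \code{n_codons} sense codons is evolved
#' independently along two lineages: each site mutates with probability
#' \code{mu}; proposals creating stop codons are rejected, and
#' nonsynonymous proposals are accepted with probability
#' \code{nonsyn_factor} (1 = neutral, <1 = purifying pressure).
#'
#' @param n_codons Alignment length in codons.
#' @param mu Per-site per-lineage mutation probability.
#' @param nonsyn_factor Acceptance probability of amino-acid-changing
#'   proposals.
#' @param seed Optional seed.
#' @return List with \code{seq1}, \code{seq2} (aligned, gap-free).
#' @export
simulate_codon_evolution <- function(n_codons, mu = 0.05, nonsyn_factor = 1,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  anc <- .rand_codons(n_codons)
  evolve <- function(nt) {
    chars <- strsplit(nt, "")[[1]]
    hit <- which(stats::runif(length(chars)) < mu)
    for (p in hit) {
      b <- sample(setdiff(.BASES, chars[p]), 1)
      cstart <- p - ((p - 1L) %% 3L)
      old_codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
      cand <- chars; cand[p] <- b
      new_codon <- paste(cand[cstart:(cstart + 2L)], collapse = "")
      if (new_codon %in% .STOPS) next
      if (gc[[new_codon]] != gc[[old_codon]] &&
          stats::runif(1) > nonsyn_factor) next
      chars[p] <- b
    }
    paste(chars, collapse = "")
  }
  list(seq1 = evolve(anc), seq2 = evolve(anc))
}
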