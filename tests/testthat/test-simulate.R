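test_that("toxin pool: size one, determinism, separability", {
  cfg1 <- small_sim_config(seed = 91, pool_size = 1)
  expect_length(generate_toxin_pool(cfg1), 1L)

  cfg <- small_sim_config(seed = 91, pool_size = 10)
  p1 <- generate_toxin_pool(cfg)
  p2 <- generate_toxin_pool(cfg)
  expect_identical(p1, p2)

  # exhaustive pairwise check with the independent DP oracle (small pool,
  # short domains so the O(nm) oracle stays cheap)
  cfg_small <- small_sim_config(seed = 92, pool_size = 6,
                                domain_length_range = c(60, 90))
  pool <- generate_toxin_pool(cfg_small)
  limit <- cfg_small$cluster_threshold - cfg_small$separability_margin
  for (i in 1:5) for (j in (i + 1):6) {
    o <- oracle_overlap_align(pool[[i]], pool[[j]])
    id_max <- o$nmatch_max / min(nchar(pool[[i]]), nchar(pool[[j]]))
    expect_lt(id_max, limit)
  }

  # unsatisfiable separability fails loudly rather than looping forever:
  # random sequences can never sit below 15% identity
  cfg_bad <- small_sim_config(seed = 93, pool_size = 3,
                              cluster_threshold = 0.2,
                              separability_margin = 0.05)
  expect_error(generate_toxin_pool(cfg_bad), "separable")
})

test_that("simulation is deterministic and structurally consistent", {
  cfg <- small_sim_config(seed = 94)
  s1 <- simulate_strains(cfg)
  s2 <- simulate_strains(cfg)
  expect_identical(as.character(s1$genomes), as.character(s2$genomes))
  expect_identical(s1$truth$genes, s2$truth$genes)
  expect_identical(s1$truth$newick, s2$truth$newick)

  # independent structural re-scan: every gene record is an ATG..stop span
  # preceded by the all-frame stop pad, and the pad count equals the
  # forward-strand gene count
  tg <- s1$truth$genes
  for (st in names(s1$genomes)) {
    g <- as.character(s1$genomes[[st]])
    rows <- tg[tg$strain == st, ]
    fwd <- rows[rows$strand == "+", ]
    expect_equal(
      length(gregexpr("TAAATAAATAA(?=ATG)", g, perl = TRUE)[[1]]),
      nrow(fwd))
    for (i in seq_len(nrow(fwd))) {
      nt <- substr(g, fwd$start[i], fwd$end[i])
      expect_equal(substr(nt, 1, 3), "ATG")
      expect_true(substr(nt, nchar(nt) - 2, nchar(nt)) %in%
                    c("TAA", "TAG", "TGA"))
      expect_equal(nchar(nt) %% 3, 0)
    }
  }
})

test_that("minimal one-strain configuration yields one lead and one immunity", {
  cfg <- simulation_config(n_strains = 1, pool_size = 2,
                           loci_per_strain_range = c(1, 1),
                           orphans_per_locus_range = c(0, 0),
                           p_toxinless = 0, p_pseudogenize = 0,
                           p_orphan_immunity = 0, n_decoy_orfs = 0,
                           short_domain_controls = 0, n_housekeeping = 1,
                           seed = 95)
  sim <- simulate_strains(cfg)
  tg <- sim$truth$genes
  expect_equal(sum(grepl("^rhs_", tg$class)), 1L)
  expect_equal(tg$class[grepl("^rhs_", tg$class)], "rhs_lead")
  expect_equal(sum(tg$class == "immunity"), 1L)
  expect_equal(sim$truth$newick, "S01;")
})

test_that("zero mutation rate leaves shared domains identical across strains", {
  cfg <- small_sim_config(seed = 96, per_branch_substitution_rate = 0,
                          p_hgt = 0, p_pseudogenize = 0,
                          p_orphan_immunity = 0, short_domain_controls = 0)
  sim <- simulate_strains(cfg)
  tg <- sim$truth$genes
  tox <- tg[!is.na(tg$prototype) & grepl("^rhs_", tg$class), ]
  for (p in unique(tox$prototype)) {
    rows <- tox[tox$prototype == p, ]
    doms <- vapply(seq_len(nrow(rows)), function(i) {
      substr(as.character(sim$genomes[[rows$strain[i]]]),
             rows$domain_start[i], rows$domain_end[i])
    }, character(1))
    expect_equal(length(unique(doms)), 1L)
    expect_equal(doms[1], unname(sim$truth$pool$toxin[p]))
  }
})

test_that("strand randomisation keeps truth coordinates consistent", {
  cfg <- small_sim_config(seed = 97, randomize_strand = TRUE)
  sim <- simulate_strains(cfg)
  tg <- sim$truth$genes
  rev_rows <- tg[tg$strand == "-" & grepl("^rhs_", tg$class), ]
  expect_gt(nrow(rev_rows), 0)
  # a reverse-strand gene read as reverse complement starts with ATG
  r <- rev_rows[1, ]
  nt <- substr(as.character(sim$genomes[[r$strain]]), r$start, r$end)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  expect_equal(substr(rc, 1, 3), "ATG")
  # and detection still matches truth on the flipped loci
  st <- r$strain
  called <- detect_strain(sim, st)
  tt <- tg[tg$strain == st & grepl("^rhs_", tg$class), ]
  expect_setequal(paste(called$start, called$end, called$strand),
                  paste(tt$start, tt$end, tt$strand))
})

test_that("truth files round-trip losslessly and follow GFF3 conventions", {
  cfg <- small_sim_config(seed = 98, n_strains = 3)
  sim <- simulate_strains(cfg)
  dir <- withr::local_tempdir()
  write_truth(sim, dir)
  back <- read_truth(dir)
  expect_identical(as.character(back$genomes), as.character(sim$genomes))
  expect_equal(back$truth$genes, sim$truth$genes)
  expect_equal(back$truth$metadata, sim$truth$metadata)
  expect_equal(back$truth$t6ss, sim$truth$t6ss)
  expect_equal(back$truth$pool$toxin, sim$truth$pool$toxin)
  expect_equal(back$truth$marker_seqs$housekeeping,
               sim$truth$marker_seqs$housekeeping)
  expect_equal(back$truth$newick, sim$truth$newick)
  expect_equal(back$config$seed, sim$config$seed)

  # GFF3 is 1-based inclusive: a truth gene appears verbatim
  gff <- rtracklayer::import(file.path(dir, "truth.gff3"))
  g1 <- sim$truth$genes[1, ]
  hit <- gff[gff$ID == g1$gene_id]
  expect_equal(GenomicRanges::start(hit), g1$start)
  expect_equal(GenomicRanges::end(hit), g1$end)

  # degenerate case: truth with no strains still writes valid files
  empty <- sim
  empty$genomes <- Biostrings::DNAStringSet()
  empty$truth$genes <- NULL
  dir2 <- withr::local_tempdir()
  expect_no_error(write_truth(empty, dir2))
  expect_true(file.exists(file.path(dir2, "truth.gff3")))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_strains = 0), "n_strains")
  expect_error(simulation_config(tree_mode = "fixed_newick"), "newick")
  expect_error(simulation_config(core_length_range = c(50, 60)),
               "too short")
})
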