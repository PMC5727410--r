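mutate_aa <- function(aa, frac) {
  chars <- strsplit(aa, "")[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  idx <- sample(length(chars), round(frac * length(chars)))
  for (i in idx) chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
  paste(chars, collapse = "")
}

test_that("presence matrix scores, thresholds and per-query overrides", {
  set.seed(71)
  gene <- random_aa(200)
  diverged <- mutate_aa(gene, 0.40)         # ~60% identity
  proteomes <- list(
    gA = c(o1 = gene, o2 = random_aa(120)),
    gB = c(o1 = diverged, o2 = random_aa(150)),
    gC = c(o1 = random_aa(180)))
  pm <- presence_matrix(c(q = gene), proteomes)
  expect_true(all(pm$score == pm$identity * pm$coverage))
  expect_true(pm$present[pm$genome == "gA"])
  expect_equal(pm$identity[pm$genome == "gA"], 1.0)
  expect_false(pm$present[pm$genome == "gC"])
  # a 60%-identity hit passes the default floor but fails a 70% override
  row_b <- pm[pm$genome == "gB", ]
  expect_true(row_b$identity > 0.5 && row_b$identity < 0.7)
  expect_true(row_b$present)
  pm_ov <- presence_matrix(c(q = gene), proteomes,
                           overrides = list(q = list(id = 0.7)))
  expect_false(pm_ov$present[pm_ov$genome == "gB"])
  # monotone: raising floors never increases the number of present calls
  pm_hi <- presence_matrix(c(q = gene), proteomes, id_min = 0.9,
                           cov_min = 0.9)
  expect_lte(sum(pm_hi$present), sum(pm$present))
  # score matrix attribute
  m <- attr(pm, "score_matrix")
  expect_equal(dim(m), c(1L, 3L))
  expect_equal(m["q", "gA"], 1.0)
})

test_that("T6SS status calls follow the core-gene fraction rule", {
  core <- sprintf("c%02d", 1:13)
  pm <- expand.grid(query = core, genome = c("g1", "g2", "g3"),
                    stringsAsFactors = FALSE)
  pm$present <- c(rep(TRUE, 13),                   # all 13
                  rep(c(TRUE, FALSE), c(5, 8)),    # 5 of 13
                  rep(FALSE, 13))                  # none
  st <- t6ss_status(pm, systems = list(t6ss1 = core))
  expect_equal(st$status[match(c("g1", "g2", "g3"), st$genome)],
               c("present", "partial", "absent"))
  expect_equal(st$n_present[st$genome == "g2"], 5L)
})

test_that("presence of planted T6SS loci matches simulation truth", {
  cfg <- small_sim_config(seed = 72, n_strains = 5,
                          t6ss1_absent = c(4, 5), t6ss23_absent = 5,
                          loci_when_no_t6ss1_range = c(0, 0),
                          n_decoy_orfs = 3)
  sim <- simulate_strains(cfg)
  truth_t6 <- sim$truth$t6ss
  tg <- sim$truth$genes
  ref <- tg[tg$strain == "S01" & tg$class %in% c("t6ss1", "t6ss23"), ]
  proteomes <- list(); queries <- character(0)
  for (st in names(sim$genomes)) {
    o <- find_orfs(as.character(sim$genomes[[st]]), min_aa_len = 60,
                   contig_id = st)
    proteomes[[st]] <- setNames(o$aa, o$orf_id)
    if (st == "S01") {
      idx <- match(paste(ref$start, ref$end), paste(o$start, o$end))
      queries <- setNames(o$aa[idx], sub("^S01_", "", ref$gene_id))
    }
  }
  pm <- presence_matrix(queries, proteomes)
  st <- t6ss_status(pm, systems = list(
    t6ss1 = grep("^tss", names(queries), value = TRUE),
    t6ss23 = grep("^t2_", names(queries), value = TRUE)))
  for (i in seq_len(nrow(truth_t6))) {
    s <- truth_t6$strain[i]
    expect_equal(
      st$status[st$genome == s & st$system == "t6ss1"] == "present",
      truth_t6$t6ss1[i])
    expect_equal(
      st$status[st$genome == s & st$system == "t6ss23"] == "present",
      truth_t6$t6ss23[i])
  }
})

test_that("toxin/immunity co-occurrence: violations only when planted", {
  set.seed(73)
  tox <- random_aa(150); imm <- random_aa(110)
  pairs <- data.frame(pair_id = "p1", toxin_aa = tox, immunity_aa = imm,
                      stringsAsFactors = FALSE)
  proteomes <- list(
    both = c(a = tox, b = imm),
    immunity_only = c(b = imm, junk = random_aa(100)),
    neither = c(x = random_aa(130)),
    toxin_only = c(a = tox))
  cooc <- toxin_immunity_cooccurrence(pairs, proteomes)
  get <- function(g) cooc[cooc$genome == g, ]
  expect_true(get("both")$toxin_present && get("both")$immunity_present)
  expect_false(get("both")$violation)
  expect_true(get("immunity_only")$immunity_present)
  expect_false(get("immunity_only")$toxin_present)
  expect_false(get("immunity_only")$violation)
  expect_false(get("neither")$toxin_present ||
                 get("neither")$immunity_present)
  expect_true(get("toxin_only")$violation)
  expect_error(toxin_immunity_cooccurrence(
    data.frame(pair_id = "p", toxin_aa = tox, immunity_aa = NA),
    proteomes), "toxinless")
})

test_that("inter-locus mean identity on identical, related and random loci", {
  set.seed(74)
  locus <- setNames(vapply(1:4, function(i) random_aa(150), character(1)),
                    paste0("g", 1:4))
  same <- interlocus_mean_identity(locus, locus)
  expect_equal(same$mean_identity, 1.0)
  expect_equal(same$n_matched, 4L)
  # unrelated loci: no hits above the floor
  other <- setNames(vapply(1:4, function(i) random_aa(150), character(1)),
                    paste0("h", 1:4))
  none <- interlocus_mean_identity(locus, other)
  expect_true(is.na(none$mean_identity))
  expect_equal(none$n_matched, 0L)
  # half of each query conserved: value = identity * aligned fraction
  half <- setNames(vapply(locus, function(a) {
    paste0(substr(a, 1, 75), random_aa(75))
  }, character(1)), paste0("m", 1:4))
  got <- interlocus_mean_identity(locus, half)
  expect_equal(got$n_matched, 4L)
  expect_true(all(abs(got$per_gene$value - 0.5) < 0.1))
})

test_that("Rhs counts per strain are grouped by T6SS complement", {
  genes <- data.frame(strain = c("s1", "s1", "s1", "s2", "s3"),
                      gene_id = paste0("g", 1:5), stringsAsFactors = FALSE)
  status <- expand.grid(genome = c("s1", "s2", "s3", "s4"),
                        system = c("t6ss1", "t6ss23"),
                        stringsAsFactors = FALSE)
  status$status <- c("present", "present", "absent", "absent",   # t6ss1
                     "present", "absent", "present", "absent")   # t6ss23
  counts <- rhs_count_by_t6ss_group(genes, status,
                                    strains = c("s1", "s2", "s3", "s4"))
  expect_equal(counts$n_rhs, c(3L, 1L, 1L, 0L))
  expect_equal(counts$group,
               c("both", "t6ss1_only", "t6ss23_only", "neither"))
  # empty input
  empty <- rhs_count_by_t6ss_group(genes[0, ], status,
                                   strains = c("s1", "s2"))
  expect_equal(empty$n_rhs, c(0L, 0L))
})
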