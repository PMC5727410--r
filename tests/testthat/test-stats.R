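# Independent bipartition-based RF oracle: tip sets under each internal
# edge, symmetric difference of the two split sets.
oracle_rf <- function(t1, t2) {
  splits <- function(tr) {
    tr <- ape::unroot(tr)
    n <- length(tr$tip.label)
    tips_below <- function(node) {
      if (node <= n) return(tr$tip.label[node])
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      unlist(lapply(kids, tips_below))
    }
    internal <- tr$edge[tr$edge[, 2] > n, 2]
    out <- lapply(internal, function(nd) {
      s <- sort(tips_below(nd))
      comp <- sort(setdiff(tr$tip.label, s))
      # canonical form: lexicographically smaller side first
      if (paste(comp, collapse = ",") < paste(s, collapse = ",")) s <- comp
      paste(s, collapse = ",")
    })
    unique(unlist(out))
  }
  s1 <- splits(t1); s2 <- splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

test_that("TPM columns sum to one million and match hand values", {
  t1 <- tpm(matrix(c(10, 10), ncol = 1), c(1000, 1000))
  expect_equal(as.numeric(t1), c(5e5, 5e5))
  t2 <- tpm(matrix(c(10, 10), ncol = 1), c(1000, 2000))
  expect_equal(as.numeric(t2), c(2e6 / 3, 1e6 / 3))
  expect_equal(as.numeric(tpm(matrix(5), 300)), 1e6)
  set.seed(81)
  counts <- matrix(rpois(60, 50), ncol = 3)
  out <- tpm(counts, sample(200:2000, 20))
  expect_equal(unname(colSums(out)), rep(1e6, 3))
  expect_error(tpm(matrix(c(0, 0), ncol = 1), c(100, 100)), "all-zero")
})

test_that("Spearman correlation: monotone extremes and rank oracle", {
  x <- 1:10
  expect_equal(spearman_correlation(x, rev(x))$rho, -1)
  expect_equal(spearman_correlation(x, x)$rho, 1)
  expect_equal(spearman_correlation(x, x)$p, 0)
  set.seed(82)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    got <- spearman_correlation(a, b)
    # rank-then-Pearson oracle
    expect_equal(got$rho, cor(rank(a), rank(b)))
    ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
    expect_equal(got$rho, unname(ct$estimate))
  }
  expect_true(is.na(spearman_correlation(rep(1, 5), 1:5)$rho))
  expect_error(spearman_correlation(1:2, 2:1), "n >= 3")
})

test_that("one-way ANOVA with Tukey HSD: null, t-test identity, power", {
  # identical groups: F = 0, everything non-significant
  null <- anova_tukey(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(null$F, 0)
  expect_equal(null$p, 1)
  expect_true(all(null$tukey$p_adj == 1))
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(83)
  v <- c(rnorm(8), rnorm(8, 1))
  g <- rep(c("a", "b"), each = 8)
  at <- anova_tukey(v, g)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(at$F, unname(tt$statistic)^2)
  expect_equal(at$p, tt$p.value)
  # a planted +20 shift at sigma 5 is detected by the pairwise contrast
  set.seed(84)
  hits <- vapply(1:40, function(i) {
    vals <- c(rnorm(10, 30, 5), rnorm(10, 10, 5), rnorm(10, 10, 5))
    grp <- rep(c("t6ss1", "none", "t6ss23"), each = 10)
    res <- anova_tukey(vals, grp)
    res$tukey$p_adj[res$tukey$comparison == "t6ss1-none"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  expect_error(anova_tukey(1:3, rep("a", 3)), "two groups")
})

test_that("NG86 dN/dS matches hand-counted fixtures", {
  # identical sequences: no differences, omega undefined
  same <- ng86_dnds("TTTAAAGGG", "TTTAAAGGG")
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_equal(same$status, "identical")

  # one synonymous (TTT>TTC) and one nonsynonymous (AAA>GAA) difference;
  # expected values hand-counted with stop-excluded site denominators
  fx <- ng86_dnds("TTTAAAGGGCCCATGGATCGT", "TTCGAAGGGCCCATGGATCGT")
  expect_equal(fx$S, 4.0)
  expect_equal(fx$N, 17.0)
  expect_equal(fx$Sd, 1.0)
  expect_equal(fx$Nd, 1.0)
  expect_equal(fx$dS, 0.30409883108112323)
  expect_equal(fx$dN, 0.061258523260700345)
  expect_equal(fx$omega, fx$dN / fx$dS)

  pad <- "GGGCCCATGAAACTGGATCGTACTTAT"
  # synonymous-only divergence: omega = 0
  syn <- ng86_dnds(paste0("TTT", pad), paste0("TTC", pad))
  expect_equal(syn$dN, 0)
  expect_equal(syn$dS, 0.15050302159661344)
  expect_equal(syn$omega, 0)
  # nonsynonymous-only divergence: dS = 0, omega undefined/infinite
  nonsyn <- ng86_dnds(paste0("AAA", pad), paste0("GAA", pad))
  expect_equal(nonsyn$dS, 0)
  expect_equal(nonsyn$dN, 0.04546846636232614)
  expect_equal(nonsyn$status, "dS_zero")
  expect_true(is.na(nonsyn$omega))
  # two-position codon difference: equally weighted mutational pathways
  two <- ng86_dnds(paste0("TTT", pad), paste0("GTA", pad))
  expect_equal(two$Sd, 0.5)
  expect_equal(two$Nd, 1.5)
  expect_equal(two$dS, 0.06822883365429497)
  expect_equal(two$dN, 0.07036406641324114)
  # gap columns are skipped
  gap <- ng86_dnds(paste0("---", pad), paste0("TTC", pad))
  expect_equal(gap$n_codons, nchar(pad) / 3)
})

test_that("omega calibration: neutral near 1, purifying well below", {
  set.seed(85)
  neutral <- vapply(1:5, function(i) {
    p <- simulate_codon_evolution(300, mu = 0.04, nonsyn_factor = 1)
    ng86_dnds(p$seq1, p$seq2)$omega
  }, numeric(1))
  # single-replicate omega at 300 codons is noisy (sd ~0.3); the mean is
  # the calibrated quantity
  expect_gt(mean(neutral), 0.7)
  expect_lt(mean(neutral), 1.4)
  purifying <- vapply(1:5, function(i) {
    p <- simulate_codon_evolution(300, mu = 0.04, nonsyn_factor = 0.2)
    ng86_dnds(p$seq1, p$seq2)$omega
  }, numeric(1))
  expect_true(all(purifying < 0.45))
  expect_true(mean(purifying) < mean(neutral))
})

test_that("p-distances, NJ reconstruction and RF distance", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAT", c = "AAAAAAAATT")
  d <- pdistance_matrix(seqs)
  expect_equal(d["a", "b"], 0.1)
  expect_equal(d["a", "c"], 0.2)
  expect_equal(d["b", "c"], 0.1)
  expect_true(isSymmetric(d))
  # gap/N positions excluded pairwise
  d2 <- pdistance_matrix(c(x = "AA-A", y = "AATA"))
  expect_equal(d2["x", "y"], 0)

  # additive four-taxon matrix: NJ recovers topology and branch lengths
  dm <- matrix(c(0, 3, 7, 8,
                 3, 0, 8, 9,
                 7, 8, 0, 5,
                 8, 9, 5, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(dm)
  expect_equal(sort(tr$tip.label), letters[1:4])
  expect_equal(oracle_rf(tr, ape::read.tree(text = "((a,b),(c,d));")), 0)
  # reconstructed path lengths reproduce the input distances
  ct <- ape::cophenetic.phylo(tr)
  expect_equal(ct[letters[1:4], letters[1:4]], dm, tolerance = 1e-10)

  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
  # random trees: agreement with the bipartition enumeration oracle
  set.seed(86)
  for (i in 1:8) {
    r1 <- ape::rtree(8); r2 <- ape::rtree(8)
    expect_equal(rf_distance(r1, r2), oracle_rf(r1, r2))
  }
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "3 taxa")
})
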