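test_that("every intact simulated toxin pairs with its planted immunity gene", {
  sim <- simulate_strains(small_sim_config(seed = 51))
  truth <- sim$truth$genes
  for (st in names(sim$genomes)[1:3]) {
    genes <- detect_strain(sim, st)
    orfs <- find_orfs(as.character(sim$genomes[[st]]), min_aa_len = 60,
                      contig_id = st)
    pairs <- pair_immunity(genes, orfs)
    timm <- truth[truth$strain == st & truth$class == "immunity" &
                    !is.na(truth$cognate), ]
    # restrict to intact toxins: a pseudogene's ORF stops at its lesion,
    # leaving its immunity gene outside the pairing window
    tox <- truth[match(timm$cognate, truth$gene_id), ]
    keep <- !tox$pseudogene
    timm <- timm[keep, ]; tox <- tox[keep, ]
    called_key <- paste(genes$start, genes$end)
    pair_idx <- match(paste(tox$start, tox$end), called_key)
    expect_false(anyNA(pair_idx))
    got <- pairs[match(genes$gene_id[pair_idx], pairs$toxin_id), ]
    expect_equal(got$immunity_start, timm$start)
    expect_equal(got$immunity_end, timm$end)
    expect_true(all(got$distance_nt == sim$config$spacer_nt))
    # toxinless genes never get an immunity call
    expect_false(any(pairs$architecture == "toxinless"))
  }
})

test_that("strand rule and tie-breaks in immunity pairing", {
  gene <- data.frame(orf_id = "t", contig = "c", gene_id = "t",
                     start = 101L, end = 400L, strand = "+",
                     nt = "A", aa = "M", aa_len = 1L, has_paar = TRUE,
                     core_start = 1L, core_end = 10L, n_repeats = 6L,
                     motif_start = 1L, motif_end = 26L, pseudogene = FALSE,
                     locus_id = "L", position_in_locus = 0L,
                     architecture = "lead", stringsAsFactors = FALSE)
  orf <- function(id, s, e, strand) {
    data.frame(orf_id = id, contig = "c", start = s, end = e,
               strand = strand, nt = "A", aa = "MKL", aa_len = 3L,
               stringsAsFactors = FALSE)
  }
  # only an opposite-strand candidate downstream: no call
  p <- pair_immunity(gene, orf("x", 450L, 800L, "-"))
  expect_true(is.na(p$immunity_id))
  # same-strand candidate beyond the window: no call
  p2 <- pair_immunity(gene, orf("x", 700L, 1000L, "+"))
  expect_true(is.na(p2$immunity_id))
  # nearest start wins; equal starts resolved by length
  orfs <- rbind(orf("near", 430L, 700L, "+"), orf("far", 500L, 600L, "+"))
  expect_equal(pair_immunity(gene, orfs)$immunity_id, "near")
  orfs2 <- rbind(orf("short", 430L, 600L, "+"), orf("long", 430L, 900L, "+"))
  expect_equal(pair_immunity(gene, orfs2)$immunity_id, "long")
})

test_that("forced orphan-immunity events are recovered, never the reverse", {
  cfg <- small_sim_config(seed = 52, p_orphan_immunity = 1,
                          p_orphan_pseudogenize = 0, p_pseudogenize = 0,
                          short_domain_controls = 0)
  sim <- simulate_strains(cfg)
  truth <- sim$truth$genes
  # truth invariant: no intact toxin lacks a cognate immunity gene
  tox <- truth[grepl("^rhs_", truth$class) & !truth$pseudogene &
                 truth$class != "rhs_toxinless", ]
  expect_true(all(tox$gene_id %in% truth$cognate))
  # every orphan slot became immunity-only
  orphan_truth <- truth[truth$class == "immunity" & truth$orphan_immunity, ]
  expect_gt(nrow(orphan_truth), 0)

  st <- orphan_truth$strain[1]
  genes <- detect_strain(sim, st)
  orfs <- find_orfs(as.character(sim$genomes[[st]]), min_aa_len = 60,
                    contig_id = st)
  ref <- sim$truth$pool$immunity
  ref_aa <- vapply(ref, function(nt) {
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(nt, 1, nchar(nt) - 3))))
  }, character(1))
  found <- find_orphan_immunity(orfs, Biostrings::AAStringSet(ref_aa),
                                genes, sim$genomes[st])
  ot <- orphan_truth[orphan_truth$strain == st, ]
  key <- paste(orfs$start, orfs$end)[match(found$orf_id, orfs$orf_id)]
  expect_setequal(key, paste(ot$start, ot$end))
  expect_true(all(found$orphan))
})

test_that("no orphans are reported when every toxin is intact", {
  cfg <- small_sim_config(seed = 53, p_orphan_immunity = 0,
                          p_pseudogenize = 0, short_domain_controls = 0)
  sim <- simulate_strains(cfg)
  st <- "S01"
  genes <- detect_strain(sim, st)
  orfs <- find_orfs(as.character(sim$genomes[[st]]), min_aa_len = 60,
                    contig_id = st)
  ref <- sim$truth$pool$immunity
  ref_aa <- vapply(ref, function(nt) {
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(nt, 1, nchar(nt) - 3))))
  }, character(1))
  found <- find_orphan_immunity(orfs, Biostrings::AAStringSet(ref_aa),
                                genes, sim$genomes[st])
  expect_equal(nrow(found), 0L)
})

test_that("orphaned immunity genes with nonsense lesions are flagged", {
  cfg <- small_sim_config(seed = 54, p_orphan_immunity = 1,
                          p_orphan_pseudogenize = 1, p_pseudogenize = 0,
                          short_domain_controls = 0)
  sim <- simulate_strains(cfg)
  truth <- sim$truth$genes
  ot <- truth[truth$class == "immunity" & truth$orphan_immunity &
                truth$pseudogene, ]
  expect_gt(nrow(ot), 0)
  st <- ot$strain[1]
  genes <- detect_strain(sim, st)
  orfs <- find_orfs(as.character(sim$genomes[[st]]), min_aa_len = 60,
                    contig_id = st)
  ref <- sim$truth$pool$immunity
  ref_aa <- vapply(ref, function(nt) {
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(nt, 1, nchar(nt) - 3))))
  }, character(1))
  found <- find_orphan_immunity(orfs, Biostrings::AAStringSet(ref_aa),
                                genes, sim$genomes[st])
  expect_gt(nrow(found), 0)
  expect_true(all(found$orphan))
  expect_true(any(found$pseudogene))
})

test_that("pseudogene flagging against a full-length homolog", {
  set.seed(55)
  aa_full <- random_aa(120)
  codon_of <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  nt_full <- paste(codon_of[strsplit(aa_full, "")[[1]]], collapse = "")
  # intact copy: ORF spans the whole homolog
  contig <- paste0("ATG", nt_full, "TAA")
  orf <- list(start = 1L, end = nchar(contig), strand = "+",
              aa = paste0("M", aa_full))
  r <- flag_pseudogene(orf, paste0("M", aa_full), contig)
  expect_false(r$pseudogene)
  # single premature stop at 50% of the homolog
  nt_lesion <- nt_full
  substr(nt_lesion, 181, 183) <- "TAA"   # codon 61 of the homolog body
  contig2 <- paste0("ATG", nt_lesion, "TAA")
  orf2 <- list(start = 1L, end = 186L, strand = "+",
               aa = paste0("M", substr(aa_full, 1, 60)))
  r2 <- flag_pseudogene(orf2, paste0("M", aa_full), contig2)
  expect_true(r2$pseudogene)
  expect_equal(length(r2$lesions), 1L)
  expect_equal(r2$lesions, 62L)
  # homolog no longer than the ORF: FALSE by definition
  r3 <- flag_pseudogene(orf, "MSHORT", contig)
  expect_false(r3$pseudogene)
  # frame runs off the contig: indeterminate
  r4 <- flag_pseudogene(orf2, paste0("M", aa_full, random_aa(200)), contig2)
  expect_true(is.na(r4$pseudogene))
})
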