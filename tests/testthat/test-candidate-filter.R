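test_that("counts_to_tpm follows the TPM formula", {
  tpm <- counts_to_tpm(c(g1 = 10, g2 = 10), c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(sum(tpm), 1e6)
  # single expressed gene takes the whole million
  expect_equal(unname(counts_to_tpm(c(g = 3.5), c(g = 800))), 1e6)
  # degenerate all-zero counts
  expect_equal(unname(counts_to_tpm(c(a = 0, b = 0), c(a = 100, b = 100))),
               c(0, 0))
  expect_error(counts_to_tpm(c(a = 1), c(a = 0)), "positive")
  expect_error(counts_to_tpm(c(a = 1), c(b = 10)), "no length")
})

test_that("TPM normalization sums to one million for random inputs", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    counts <- setNames(runif(n, 0, 100), paste0("g", 1:n))
    lens <- setNames(sample(200:5000, n), paste0("g", 1:n))
    expect_equal(sum(counts_to_tpm(counts, lens)), 1e6, tolerance = 1e-6)
  }
})

test_that("hla_genotype validates allele syntax and count", {
  expect_s3_class(hla_genotype(c("HLA-A*02:01", "HLA-B*07:02")),
                  "hla_genotype")
  expect_error(hla_genotype("HLA-E*01:01"), "invalid")
  expect_error(hla_genotype("A*02:01"), "invalid")
  expect_error(hla_genotype(character()), "1-6")
})

scored_fixture <- function() {
  set.seed(51)
  prot <- setNames(random_protein(300), "PR")
  pairs <- peptide_candidates(
    make_variants("PR", 100, substr(prot, 100, 100), "W",
                  list(c("mutect2", "strelka2")), gene_id = "G1"),
    prot)
  hla <- hla_genotype(c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*07:02",
                        "HLA-B*08:01", "HLA-C*07:01", "HLA-C*07:02"))
  list(pairs = pairs, hla = hla)
}

test_that("scoring takes the peptide x allele product with gene TPM", {
  fx <- scored_fixture()
  const <- structure(function(p, a) rep(50, length(p)),
                     class = c("rank_provider", "function"))
  sc <- score_candidates(fx$pairs, fx$hla, const, c(G1 = 7.5))
  expect_equal(nrow(sc), 38 * 6)
  expect_true(all(sc$rank_pct == 50))
  expect_true(all(sc$tpm == 7.5))
  # gene absent from the table scores TPM 0
  sc0 <- score_candidates(fx$pairs, fx$hla, const, c(OTHER = 3))
  expect_true(all(sc0$tpm == 0))
})

test_that("the surrogate provider is deterministic, seed-sensitive, in (0,100]", {
  p1 <- rank_provider_surrogate(7)
  p2 <- rank_provider_surrogate(7)
  p3 <- rank_provider_surrogate(8)
  peps <- replicate(50, random_protein(9))
  r1 <- p1(peps, rep("HLA-A*02:01", 50))
  expect_identical(r1, p2(peps, rep("HLA-A*02:01", 50)))
  expect_false(identical(r1, p3(peps, rep("HLA-A*02:01", 50))))
  expect_true(all(r1 > 0 & r1 <= 100))
  # allele matters
  expect_false(identical(r1, p1(peps, rep("HLA-B*07:02", 50))))
})

test_that("threshold selection applies strict rank and TPM cuts", {
  sc <- data.frame(gene_id = "G", protein_id = "P", protein_pos = 1,
                   aa_ref = "A", aa_alt = "V", length = 9,
                   offset_in_window = 0,
                   mut_peptide = paste0("PEP", 1:4), wt_peptide = "W",
                   allele = "HLA-A*02:01",
                   rank_pct = c(0.5, 0.1, 0.49, 0.3),
                   tpm = c(5, 0.5, 5, 1.0), stringsAsFactors = FALSE)
  out <- select_candidates(sc, selection_config("threshold"))
  # rank 0.5 exactly fails (<), tpm 0.5 fails (>1), tpm 1.0 exactly fails
  expect_equal(out$mut_peptide, "PEP3")
})

test_that("top-N selection keeps best allele per peptide, n_top sequences", {
  set.seed(60)
  peps <- replicate(200, random_protein(9))
  sc <- expand.grid(mut_peptide = peps,
                    allele = c("HLA-A*01:01", "HLA-A*02:01"),
                    stringsAsFactors = FALSE)
  sc$gene_id <- "G"; sc$tpm <- NA_real_
  sc$rank_pct <- runif(nrow(sc), 0.01, 30)
  out <- select_candidates(sc, selection_config("top_n", n_top = 150))
  expect_equal(nrow(out), 150)
  expect_false(anyDuplicated(out$mut_peptide) > 0)
  expect_true(!is.unsorted(out$rank_pct))
  # each kept row is that peptide's best allele
  for (i in sample(nrow(out), 10)) {
    both <- sc$rank_pct[sc$mut_peptide == out$mut_peptide[i]]
    expect_equal(out$rank_pct[i], min(both))
  }
})

test_that("selection is monotone in its thresholds and idempotent", {
  set.seed(61)
  sc <- data.frame(gene_id = "G", mut_peptide = replicate(300, random_protein(9)),
                   allele = "HLA-A*02:01",
                   rank_pct = runif(300, 0, 5), tpm = rlnorm(300, 0, 2),
                   stringsAsFactors = FALSE)
  base <- select_candidates(sc, selection_config("threshold"))
  tighter_rank <- select_candidates(
    sc, selection_config("threshold", rank_threshold_pct = 0.25))
  higher_tpm <- select_candidates(
    sc, selection_config("threshold", tpm_threshold = 4))
  expect_true(all(tighter_rank$mut_peptide %in% base$mut_peptide))
  expect_true(all(higher_tpm$mut_peptide %in% base$mut_peptide))
  n50 <- select_candidates(sc, selection_config("top_n", n_top = 50))
  n100 <- select_candidates(sc, selection_config("top_n", n_top = 100))
  expect_true(all(n50$mut_peptide %in% n100$mut_peptide))
  again <- select_candidates(base, selection_config("threshold"))
  expect_equal(again$mut_peptide, base$mut_peptide)
})

test_that("planted strong binders survive threshold selection when expressed", {
  set.seed(62)
  fx <- scored_fixture()
  planted <- fx$pairs$mut_peptide[c(3, 17)]
  prov <- rank_provider_planted(rank_provider_surrogate(1), planted, 0.1)
  sc <- score_candidates(fx$pairs, fx$hla, prov, c(G1 = 10))
  out <- select_candidates(sc, selection_config("threshold"))
  expect_true(all(planted %in% out$mut_peptide))
})

test_that("the table provider serves stored ranks and fails loudly on misses", {
  tab <- data.frame(peptide = c("AAA", "BBB"), allele = "HLA-A*02:01",
                    rank_pct = c(0.2, 3))
  prov <- rank_provider_table(tab)
  expect_equal(prov(c("BBB", "AAA"), rep("HLA-A*02:01", 2)), c(3, 0.2))
  expect_error(prov("CCC", "HLA-A*02:01"), "CCC.*HLA-A\\*02:01")
})
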