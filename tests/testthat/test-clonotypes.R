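rearr_row <- function(cell, sample, locus, v, j, junction) {
  data.frame(cell_id = cell, sample_id = sample, locus = locus,
             v_call = v, j_call = j, junction_aa = junction,
             stringsAsFactors = FALSE)
}

two_sample_sheet <- function(n1 = 266L, n2 = 158L) {
  data.frame(sample_id = c("s1", "s2"), patient = "pt",
             compartment = c("tumor", "adjacent_bladder"),
             timepoint = c("pre_bcg", "pre_bcg"),
             n_cells = c(n1, n2), stringsAsFactors = FALSE)
}

test_that("cells sharing a TRB merge even when one lacks the TRA", {
  rearr <- rbind(
    rearr_row("c1", "s1", "TRB", "TRBV9*01", "TRBJ1-1*01", "CASSF"),
    rearr_row("c1", "s1", "TRA", "TRAV1*01", "TRAJ6*01", "CAVF"),
    rearr_row("c2", "s1", "TRB", "TRBV9*02", "TRBJ1-1*01", "CASSF"))
  ct <- build_clonotype_table(rearr, two_sample_sheet())
  expect_equal(nrow(ct$clonotypes), 1)       # allele-level difference ignored
  expect_equal(unname(ct$counts[1, "s1"]), 2)
  expect_false(ct$detected[1, "s2"])
})

test_that("cells with two distinct TRBs are dropped as doublets", {
  rearr <- rbind(
    rearr_row("c1", "s1", "TRB", "TRBV9*01", "TRBJ1-1*01", "CASSF"),
    rearr_row("c1", "s1", "TRB", "TRBV2*01", "TRBJ2-2*01", "CATTF"),
    rearr_row("c2", "s1", "TRB", "TRBV9*01", "TRBJ1-1*01", "CASSF"))
  expect_warning(ct <- build_clonotype_table(rearr, two_sample_sheet()),
                 "doublet")
  expect_equal(sum(ct$counts), 1)
})

test_that("TRA-only cells are excluded and ambiguous TRB pairings kept apart", {
  rearr <- rbind(
    rearr_row("c0", "s1", "TRA", "TRAV1*01", "TRAJ6*01", "CAVF"),
    rearr_row("c1", "s1", "TRB", "TRBV9*01", "TRBJ1-1*01", "CASSF"),
    rearr_row("c1", "s1", "TRA", "TRAV1*01", "TRAJ6*01", "CAVF"),
    rearr_row("c2", "s1", "TRB", "TRBV9*01", "TRBJ1-1*01", "CASSF"),
    rearr_row("c2", "s1", "TRA", "TRAV3*01", "TRAJ9*01", "CALF"),
    rearr_row("c3", "s1", "TRB", "TRBV9*01", "TRBJ1-1*01", "CASSF"))
  ct <- build_clonotype_table(rearr, two_sample_sheet())
  # two paired clonotypes share the TRB; the TRB-only cell stays separate
  expect_equal(nrow(ct$clonotypes), 3)
  expect_true(any(ct$clonotypes$ambiguous_trb))
  expect_equal(sum(ct$counts), 3)            # TRA-only cell not counted
})

test_that("frequencies divide counts by sample depth with a detection floor", {
  counts <- matrix(c(2L, 0L), 1, dimnames = list("K", c("s1", "s2")))
  ct <- make_ct(counts, c(266L, 158L))
  f <- clonotype_frequencies(ct, "s1")
  expect_equal(unname(f["K"]), 2 / 266, tolerance = 1e-9)
  expect_equal(attr(f, "detection_floor"), 1 / 266)
  expect_equal(unname(clonotype_frequencies(ct, "s2")["K"]), 0)
  full <- make_ct(matrix(c(266L, 0L), 1,
                         dimnames = list("K", c("s1", "s2"))),
                  c(266L, 158L))
  expect_equal(unname(clonotype_frequencies(full, "s1")["K"]), 1)
})

test_that("pre/post comparison uses Fisher exact and floor-bounded folds", {
  counts <- matrix(c(10L, 0L, 5L, 5L, 0L, 0L), 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("pre", "post")))
  ct <- make_ct(counts, c(266L, 158L), timepoints = c("pre_bcg", "post_bcg"))
  r <- compare_timepoints(ct, "A", "pre", "post")
  expect_true(r$significant)
  expect_true(r$fold_is_bound)
  expect_equal(r$fold_change, (10 / 266) / (1 / 158), tolerance = 1e-9)
  expect_equal(r$p_value, oracle_fisher(10, 256, 0, 158), tolerance = 1e-9)
  # identical frequencies at identical depths
  ct2 <- make_ct(matrix(c(5L, 5L), 1, dimnames = list("A", c("pre", "post"))),
                 c(100L, 100L), timepoints = c("pre_bcg", "post_bcg"))
  r2 <- compare_timepoints(ct2, "A", "pre", "post")
  expect_equal(r2$p_value, 1)
  expect_equal(r2$fold_change, 1)
  expect_false(r2$fold_is_bound)
  # absent from both samples: undefined
  expect_null(compare_timepoints(ct, "C", "pre", "post"))
})

test_that("comparison p-values match the log-space oracle at deep margins", {
  set.seed(99)
  for (i in 1:40) {
    n_pre <- sample(50:500, 1); n_post <- sample(30:500, 1)
    k_pre <- rbinom(1, n_pre, runif(1, 0, 0.2))
    k_post <- rbinom(1, n_post, runif(1, 0, 0.2))
    if (k_pre + k_post == 0) k_pre <- 1
    counts <- matrix(c(k_pre, k_post), 1,
                     dimnames = list("K", c("pre", "post")))
    ct <- make_ct(counts, c(n_pre, n_post),
                  timepoints = c("pre_bcg", "post_bcg"))
    r <- compare_timepoints(ct, "K", "pre", "post")
    expect_equal(r$p_value,
                 oracle_fisher_log(k_pre, n_pre - k_pre, k_post,
                                   n_post - k_post),
                 tolerance = 1e-7)
  }
})

test_that("enrichment requires detection and dominance over all references", {
  counts <- matrix(c(13L, 0L, 0L,    # 5% tumor, absent elsewhere
                     5L, 8L, 0L,     # 2% tumor, 3% blood
                     1L, 0L, 0L),    # singleton: not detected
                   3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"),
                                   c("tumor", "adj", "blood")))
  ct <- make_ct(counts, c(266L, 158L, 266L))
  enr <- enrichment_screen(ct, "tumor", c("adj", "blood"))
  expect_equal(enr$clonotype_key, "A")
})

test_that("bulk TRB matching joins on gene-level keys with ambiguity flags", {
  rearr <- rbind(
    rearr_row("c1", "s1", "TRB", "TRBV9*01", "TRBJ1-1*01", "CASSF"),
    rearr_row("c1", "s1", "TRA", "TRAV1*01", "TRAJ6*01", "CAVF"),
    rearr_row("c2", "s1", "TRB", "TRBV9*01", "TRBJ1-1*01", "CASSF"),
    rearr_row("c2", "s1", "TRA", "TRAV3*01", "TRAJ9*01", "CALF"),
    rearr_row("c3", "s1", "TRB", "TRBV2*01", "TRBJ2-2*01", "CATTF"))
  ct <- build_clonotype_table(rearr, two_sample_sheet())
  bulk <- data.frame(v_call = "TRBV9", j_call = "TRBJ1-1",
                     junction_aa = "CASSF", frequency = 1e-4,
                     stringsAsFactors = FALSE)
  m <- match_bulk_trb(ct, bulk)
  shared <- m[m$trb_key == "TRBV9_TRBJ1-1_CASSF", ]
  expect_equal(nrow(shared), 2)
  expect_true(all(shared$bulk_frequency == 1e-4))
  expect_true(all(shared$ambiguous_match))
  absent <- m[m$trb_key == "TRBV2_TRBJ2-2_CATTF", ]
  expect_false(absent$detected_in_bulk)
  expect_equal(absent$bulk_frequency, 1e-4)   # bulk detection floor
})

test_that("per-sample clonotype counts never exceed the sample depth", {
  fx <- uc1_like_fixture()
  ct <- build_clonotype_table(fx$rearrangements, fx$samples)
  totals <- colSums(ct$counts)
  expect_true(all(totals <= fx$samples$n_cells[
    match(colnames(ct$counts), fx$samples$sample_id)]))
})

test_that("the deterministic fixture has the designed repertoire shape", {
  fx <- uc1_like_fixture()
  ct <- build_clonotype_table(fx$rearrangements, fx$samples)
  expect_equal(nrow(ct$clonotypes), 48)
  expect_equal(sum(ct$counts[, "UC1_tumor"]), 222)
  enr <- enrichment_screen(ct, "UC1_tumor", c("UC1_adjacent", "UC1_postbcg"))
  expect_setequal(enr$clonotype_key, fx$planted_enriched)
  expect_true(all(ct$counts[fx$planted_enriched, "UC1_tumor"] >= 2))
  # planted clonotypes are absent post-treatment: every fold change is a
  # floor-bounded drop
  for (k in fx$planted_enriched) {
    r <- compare_timepoints(ct, k, "UC1_tumor", "UC1_postbcg")
    expect_true(r$fold_is_bound)
    expect_gt(r$fold_change, 1)
  }
})
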