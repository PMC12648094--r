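test_that("pool assignment chunks and merges small remainders", {
  pools <- assign_pools(paste0("p", 1:150), 15)
  expect_length(pools, 10)
  expect_true(all(lengths(pools) == 15))
  pools31 <- assign_pools(paste0("p", 1:31), 15)
  expect_equal(unname(lengths(pools31)), c(15, 16))
  expect_setequal(unlist(pools31), paste0("p", 1:31))
  expect_warning(p1 <- assign_pools("solo", 15), "fewer than 2")
  expect_equal(unname(lengths(p1)), 1)
  expect_length(assign_pools(character(), 15), 0)
})

test_that("seeded shuffle is reproducible and sizes outside 10-20 warn", {
  a <- assign_pools(paste0("p", 1:40), 12, seed = 3)
  b <- assign_pools(paste0("p", 1:40), 12, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, assign_pools(paste0("p", 1:40), 12, seed = 4)))
  expect_warning(assign_pools(paste0("p", 1:12), 6), "10-20")
})

test_that("the 3-SD positivity rule is applied with strict inequality", {
  # neg mean 12, sample sd 2 -> threshold 18
  r <- call_experiment(c(18, 18, 18.3), c(10, 12, 14))
  expect_equal(r$neg_sd, 2)
  expect_true(r$positive)               # mean 18.1 > 18
  expect_false(call_experiment(c(18, 18, 18), c(10, 12, 14))$positive)
  # degenerate zero-SD negative control
  expect_true(call_experiment(c(6, 6), c(5, 5))$positive)
  expect_false(call_experiment(c(6, 6), c(5, 5), sd_floor = 1)$positive)
  expect_error(call_experiment(c(6, 6), 5), ">= 2 replicate")
})

test_that("the call is invariant to replicate order and count scaling", {
  set.seed(77)
  for (i in 1:30) {
    stim <- rpois(3, 25); neg <- rpois(3, 10)
    base <- call_experiment(stim, neg)$positive
    expect_equal(call_experiment(rev(stim), sample(neg))$positive, base)
    k <- runif(1, 0.5, 4)
    expect_equal(call_experiment(stim * k, neg * k)$positive, base)
  }
})

plates_3exp <- function(stim_means, neg = c(10, 12, 14)) {
  # one antigen "AG" tested in experiments E1..En with given replicate sets
  rows <- list()
  for (e in seq_along(stim_means)) {
    rows[[length(rows) + 1]] <- list(experiment_id = paste0("E", e),
                                     condition_id = "neg", spots = neg,
                                     kind = "negative_control")
    if (!is.na(stim_means[e])) {
      rows[[length(rows) + 1]] <- list(experiment_id = paste0("E", e),
                                       condition_id = "AG",
                                       spots = rep(stim_means[e], 3),
                                       kind = "single_peptide",
                                       members = "AG")
    }
  }
  make_plates(rows)
}

test_that("antigens need two positive experiments to be confirmed", {
  # threshold is 18: positive in E1, E2 of 3 -> confirmed
  expect_true(call_antigen("AG", plates_3exp(c(25, 25, 10)))$confirmed)
  expect_false(call_antigen("AG", plates_3exp(c(25, 10, 10)))$confirmed)
  expect_true(call_antigen("AG", plates_3exp(c(25, 25, 25)))$confirmed)
  # untested experiments are skipped, not counted negative
  r <- call_antigen("AG", plates_3exp(c(25, 25, NA)))
  expect_equal(nrow(r$per_experiment), 2)
  expect_true(r$confirmed)
  expect_error(call_antigen("GHOST", plates_3exp(c(25, 25))), "not tested")
})

decon_fixture <- function(pool_conf, singles_conf) {
  # pool P1 with 3 members; single calls per singles_conf (NA = untested)
  mk_call <- function(id, kind, members, confirmed) {
    structure(list(antigen_id = id, kind = kind, members = members,
                   per_experiment = NULL, n_positive = 2 * confirmed,
                   confirmed = confirmed,
                   status = if (confirmed) "positive" else "negative"),
              class = "response_call")
  }
  pools <- list(P1 = c("m1", "m2", "m3"))
  singles <- list()
  for (m in names(singles_conf)) {
    if (!is.na(singles_conf[[m]])) {
      singles[[m]] <- mk_call(m, "single_peptide", m, singles_conf[[m]])
    }
  }
  deconvolute(list(mk_call("P1", "pool", pools$P1, pool_conf)), singles,
              pools)
}

test_that("deconvolution attributes confirmed pools to confirmed members", {
  r <- decon_fixture(TRUE, list(m1 = TRUE, m2 = FALSE, m3 = FALSE))
  expect_equal(r$attributions$peptide, "m1")
  expect_length(r$unresolved_pools, 0)
})

test_that("a confirmed pool with all members tested negative is unresolved", {
  r <- decon_fixture(TRUE, list(m1 = FALSE, m2 = FALSE, m3 = FALSE))
  expect_equal(r$unresolved_pools, "P1")
  expect_equal(unname(r$pool_status["P1"]), "unresolved_pool")
})

test_that("untested members are pending; unconfirmed pools are not attributed", {
  r <- decon_fixture(TRUE, list(m1 = FALSE, m2 = NA, m3 = NA))
  expect_equal(sort(r$pending$peptide), c("m2", "m3"))
  expect_length(r$unresolved_pools, 0)
  r2 <- decon_fixture(FALSE, list(m1 = TRUE))
  expect_equal(nrow(r2$attributions), 0)
})

test_that("singles outside any pool are reported with a warning", {
  mk <- function(id) structure(list(antigen_id = id, kind = "single_peptide",
                                    members = id, confirmed = TRUE,
                                    n_positive = 2, status = "positive"),
                               class = "response_call")
  expect_warning(r <- deconvolute(list(), list(mk("zzz")), list()),
                 "absent from any pool")
  expect_equal(r$orphan_singles, "zzz")
})

test_that("mutant vs wild-type comparison reports direction and exact p", {
  r <- compare_mut_wt(c(10, 20, 30, 25, 18, 22), c(2, 3, 1, 2, 0, 1))
  expect_equal(r$p_value, 0.03125)
  expect_equal(r$direction, "mutant_higher")
  expect_equal(compare_mut_wt(c(5, 5), c(5, 5))$direction, "none")
})

test_that("plate CSVs round-trip and enforce one negative control", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "experiment_id,sample_source,condition_id,kind,members,well_1,well_2,well_3",
    "E1,TIL,neg,negative_control,,10,12,14",
    "E1,TIL,P1,pool,m1;m2,40,38,42",
    "E1,TIL,m1,single_peptide,m1,39,41,"), path)
  plates <- read_elispot_plates(path)
  expect_s3_class(plates, "elispot_plates")
  expect_equal(lengths(plates$spot_counts), c(3L, 3L, 2L))
  expect_true(call_antigen("P1", plates)$n_positive == 1)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("experiment_id,sample_source,condition_id,kind,members,well_1,well_2",
               "E1,TIL,P1,pool,m1;m2,40,38"), bad)
  expect_error(read_elispot_plates(bad), "negative control")
})
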