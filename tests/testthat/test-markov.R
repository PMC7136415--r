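test_that("transition counts match hand enumeration of adjacent pairs", {
  s <- encoded_sequence(c("R", "R", "A", "A", "R", "A"), rep("DAY", 6))
  tc <- count_transitions(s)
  expect_identical(tc["DAY", ], c(RR = 1L, RA = 2L, AR = 1L, AA = 1L))
  expect_identical(sum(tc), 5L)  # 5 adjacent pairs

  all_r <- encoded_sequence(rep("R", 7), rep("NIGHT", 7))
  tc2 <- count_transitions(all_r)
  expect_identical(tc2["NIGHT", "RR"], 6L)
  expect_identical(sum(tc2), 6L)

  # a transition spanning the phase boundary belongs to the origin bin
  s3 <- encoded_sequence(c("R", "A"), c("DAY", "NIGHT"))
  tc3 <- count_transitions(s3)
  expect_identical(tc3["DAY", "RA"], 1L)
  expect_identical(sum(tc3["NIGHT", ]), 0L)

  expect_error(count_transitions(encoded_sequence("R", "DAY")), "two bins")
})

test_that("pairs spanning a recording gap are never counted", {
  s <- encoded_sequence(c("R", "A", "A", "R"), rep("DAY", 4), gaps = 2L)
  tc <- count_transitions(s)
  expect_identical(sum(tc), 2L)
  expect_identical(tc["DAY", "AA"], 0L)
})

test_that("the estimator equals brute-force pair enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:20, 1)
    st <- sample(c("A", "R"), n, replace = TRUE)
    ph <- sample(c("DAY", "NIGHT"), n, replace = TRUE)
    gaps <- if (n > 3 && runif(1) < 0.5) sample(n - 1L, 1) else integer(0)
    s <- encoded_sequence(st, ph, gaps = gaps)
    expect_identical(unclass(count_transitions(s))[, ],
                     brute_force_transitions(st, ph, gaps))
  }
})

test_that("fitted probabilities and derived summaries obey the model algebra", {
  s <- encoded_sequence(c("R", "R", "A", "A", "R", "A"), rep("DAY", 6))
  fit <- suppressWarnings(fit_markov(s))
  expect_equal(fit$alpha[["DAY"]], 2 / 3)
  expect_equal(fit$beta[["DAY"]], 1 / 2)

  # alpha = 1/6 per 10-s bin means a 1-minute mean rest bout
  tc <- structure(rbind(DAY = c(RR = 5L, RA = 1L, AR = 2L, AA = 2L),
                        NIGHT = c(RR = 0L, RA = 0L, AR = 0L, AA = 0L)),
                  class = c("transition_counts", "matrix"))
  f2 <- suppressWarnings(fit_markov(tc, bin_seconds = 10))
  expect_equal(f2$alpha[["DAY"]], 1 / 6)
  expect_equal(f2$mean_rest_bout_min[["DAY"]], 1.0)

  # exact identity: activity fraction from bout means
  expect_equal(fit$average_activity[["DAY"]],
               fit$mean_activity_bout_min[["DAY"]] /
                 (fit$mean_activity_bout_min[["DAY"]] +
                    fit$mean_rest_bout_min[["DAY"]]))
})

test_that("published night bout means imply ~30% nightly activity", {
  r <- bout_means_to_rates(ref_means$ld_night$act, ref_means$ld_night$rest)
  expect_equal(r$alpha / (r$alpha + r$beta), 0.30, tolerance = 0.01)
})

test_that("phases without observations yield NaN with a classed warning", {
  s <- encoded_sequence(c("R", "R", "R"), rep("DAY", 3))
  expect_warning(fit <- fit_markov(s), class = "actimark_undefined_estimate")
  expect_true(is.nan(fit$beta[["DAY"]]))     # no A-origin pairs
  expect_true(is.nan(fit$alpha[["NIGHT"]]))  # phase absent
  expect_equal(fit$alpha[["DAY"]], 0)        # R->A never seen but defined
})

test_that("the geometric bout pmf is a proper distribution with mean 1/p", {
  expect_equal(geometric_bout_pmf(1, 1), 1)
  expect_equal(geometric_bout_pmf(1, 2), 0)
  expect_equal(geometric_bout_pmf(0.5, 1:3), c(0.5, 0.25, 0.125))
  for (p in c(0.05, 0.2, 0.7)) {
    k <- 1:5000
    pmf <- geometric_bout_pmf(p, k)
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    expect_equal(sum(k * pmf), 1 / p, tolerance = 1e-6)
  }
  expect_error(geometric_bout_pmf(0, 1), "prob")
  expect_error(geometric_bout_pmf(1.2, 1), "prob")
  expect_error(geometric_bout_pmf(0.5, 0), ">= 1")
})

test_that("bout extraction returns maximal alternating runs", {
  s <- encoded_sequence(c("R", "R", "A", "A", "A", "R"), rep("DAY", 6))
  b <- extract_bouts(s)
  expect_identical(b$state, c("R", "A", "R"))
  expect_identical(b$length_bins, c(2L, 3L, 1L))
  expect_identical(b$start_bin, c(1L, 3L, 6L))
  expect_identical(b$truncated, c(TRUE, FALSE, TRUE))

  one <- extract_bouts(encoded_sequence("A", "NIGHT"))
  expect_identical(nrow(one), 1L)
  expect_true(one$truncated)

  alt <- extract_bouts(encoded_sequence(rep(c("A", "R"), 5), rep("DAY", 10)))
  expect_identical(nrow(alt), 10L)
  expect_true(all(alt$length_bins == 1L))
})

test_that("gaps split bouts and re-truncate segment edges", {
  s <- encoded_sequence(c("A", "A", "A", "A"), rep("DAY", 4), gaps = 2L)
  b <- extract_bouts(s)
  expect_identical(b$length_bins, c(2L, 2L))
  expect_true(all(b$truncated))
})

test_that("bout counting asserts alternation and the off-by-one identity", {
  s <- encoded_sequence(c("R", "R", "A", "A", "A", "R"), rep("DAY", 6))
  b <- extract_bouts(s)
  expect_identical(count_bouts(b), 3L)
  expect_identical(count_bouts(b, "DAY"), 3L)
  expect_identical(count_bouts(b[0, ]), 0L)

  set.seed(202)
  for (i in 1:25) {
    s <- random_seq(sample(5:200, 1), p_active = runif(1, 0.2, 0.8))
    b <- extract_bouts(s)
    expect_lte(abs(sum(b$state == "A") - sum(b$state == "R")), 1)
    expect_identical(count_bouts(b), nrow(b))
  }
})

test_that("night holds more bouts than day at the published parameters", {
  # bout pair rate is 1/(mean rest + mean activity): night 1/2.50 > day 1/5.04
  set.seed(303)
  n <- 20000
  pn <- bout_means_to_rates(ref_means$ld_night$act, ref_means$ld_night$rest)
  pd <- bout_means_to_rates(ref_means$ld_day$act, ref_means$ld_day$rest)
  ph <- c(rep("DAY", n), rep("NIGHT", n))
  s <- simulate_sequence(alpha = c(DAY = pd$alpha, NIGHT = pn$alpha),
                         beta = c(DAY = pd$beta, NIGHT = pn$beta),
                         phase = ph)
  b <- extract_bouts(s)
  expect_gt(count_bouts(b, "NIGHT"), count_bouts(b, "DAY"))
})

test_that("long-run empirical rest bouts match 1/alpha bins", {
  set.seed(404)
  s <- simulate_sequence(alpha = 0.06, beta = 0.25, phase = rep("DAY", 1e6))
  b <- extract_bouts(s)
  r <- b$length_bins[b$state == "R" & !b$truncated]
  expect_equal(mean(r), 1 / 0.06, tolerance = 0.02)
})

test_that("transition counts are invariant to reordering bouts", {
  # within one phase the counts depend only on the bout-length multiset:
  # RR pairs = total R bins minus R bouts, etc., up to boundary pairs
  set.seed(505)
  lens <- sample(1:6, 20, replace = TRUE)
  states <- rep(rep(c("R", "A"), 10), times = lens)
  build <- function(st) count_transitions(encoded_sequence(st, rep("DAY", length(st))))
  tc1 <- build(states)
  perm <- sample(10)  # permute the (R, A) bout pairs
  lens_m <- matrix(lens, nrow = 2)
  st2 <- unlist(lapply(perm, function(j)
    rep(c("R", "A"), times = lens_m[, j])))
  tc2 <- build(st2)
  expect_true(all(abs(tc1 - tc2) <= 1))
  expect_identical(tc1["DAY", "RR"], tc2["DAY", "RR"])
  expect_identical(tc1["DAY", "AA"], tc2["DAY", "AA"])
})
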