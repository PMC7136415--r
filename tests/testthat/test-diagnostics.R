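test_that("split-half estimates agree on a stationary simulation", {
  set.seed(71)
  ph <- rep(rep(c("DAY", "NIGHT"), each = 500), 400)  # 4e5 bins
  s <- simulate_sequence(alpha = c(DAY = 0.04, NIGHT = 0.1),
                         beta = c(DAY = 0.31, NIGHT = 0.22), phase = ph)
  sh <- split_half_stability(s)
  rel <- abs(sh$comparison$first_half / sh$comparison$second_half - 1)
  expect_true(all(rel < 0.05))
})

test_that("a midpoint regime change shows up as disagreeing halves", {
  set.seed(72)
  n <- 5e4
  s1 <- simulate_sequence(0.05, 0.3, rep("DAY", n))
  s2 <- simulate_sequence(0.10, 0.3, rep("DAY", n))
  s <- encoded_sequence(c(s1$states, s2$states), rep("DAY", 2 * n))
  sh <- suppressWarnings(split_half_stability(s))
  a <- sh$comparison[sh$comparison$parameter == "alpha" &
                       sh$comparison$phase == "DAY", ]
  expect_equal(a$second_half / a$first_half, 2, tolerance = 0.15)
})

test_that("degenerate split input warns instead of crashing", {
  s <- encoded_sequence(c("R", "A", "R"), rep("DAY", 3))
  ws <- list()
  withCallingHandlers(
    sh <- split_half_stability(s),
    warning = function(w) {
      ws[[length(ws) + 1L]] <<- w
      invokeRestart("muffleWarning")
    })
  expect_true(any(vapply(ws, inherits, logical(1),
                         "actimark_undefined_estimate")))
  expect_true(any(is.nan(sh$comparison$first_half)))
  expect_s3_class(sh, "split_half")
})

test_that("split-half estimates correlate across a simulated cohort", {
  coh <- simulate_cohort("LD24", n_animals = 8, record_days = 5, seed = 73)
  res <- split_half_correlation(coh)
  expect_gt(res$r_alpha, 0.9)
  expect_gt(res$r_beta, 0.9)
  expect_identical(nrow(res$table), 8L * 4L)
})

test_that("conditional mutual information vanishes for memoryless sequences", {
  set.seed(81)
  # alpha = 1 - beta makes the chain an iid coin: exact independence
  s <- simulate_sequence(alpha = 0.3, beta = 0.7, phase = rep("DAY", 1e6))
  expect_lt(conditional_mutual_information(s), 1e-3)

  # any first-order chain satisfies the Markov property by construction
  s2 <- simulate_sequence(alpha = 0.08, beta = 0.25, phase = rep("NIGHT", 1e6))
  expect_lt(conditional_mutual_information(s2), 1e-3)
})

test_that("the deterministic R,R,A pattern carries 2/3 bit of memory", {
  pat <- rep(c("R", "R", "A"), 10000)
  cmi <- conditional_mutual_information(encoded_sequence(pat, rep("DAY",
                                                                  length(pat))))
  expect_equal(cmi, 2 / 3, tolerance = 1e-3)
})

test_that("cmi is non-negative, phase-splittable, and guards its inputs", {
  set.seed(82)
  for (i in 1:10) {
    s <- random_seq(sample(10:200, 1), p_active = runif(1, 0.2, 0.8))
    expect_gte(conditional_mutual_information(s), 0)
  }
  ph <- rep(c("DAY", "NIGHT"), each = 2500)
  s <- simulate_sequence(0.2, 0.3, phase = ph, seed = 4)
  res <- conditional_mutual_information(s, by_phase = TRUE)
  expect_named(res$by_phase, c("DAY", "NIGHT"))
  expect_true(all(res$by_phase >= 0))
  expect_error(conditional_mutual_information(
    encoded_sequence(c("R", "A"), c("DAY", "DAY"))), "three bins")
})

test_that("triples spanning gaps are excluded from the cmi estimate", {
  pat <- rep(c("R", "R", "A"), 2000)
  n <- length(pat)
  with_gaps <- encoded_sequence(pat, rep("DAY", n), gaps = c(10L, 1000L))
  plain <- encoded_sequence(pat, rep("DAY", n))
  expect_equal(conditional_mutual_information(with_gaps),
               conditional_mutual_information(plain), tolerance = 1e-2)
})

test_that("observed bout distributions match the model at the true parameter", {
  set.seed(91)
  s <- simulate_sequence(0.12, 0.35, rep("NIGHT", 2e5))
  fit <- suppressWarnings(fit_markov(s))
  b <- extract_bouts(s)
  tab <- bout_distribution_comparison(b, fit, "NIGHT", "R")
  expect_gt(attr(tab, "n_bouts"), 1e4)
  expect_lt(tv_distance(tab), 0.05)
  expect_equal(sum(tab$observed), 1)
  expect_equal(sum(tab$predicted) + attr(tab, "tail_mass"), 1,
               tolerance = 1e-12)
})

test_that("a two-regime rest mixture overloads both geometric tails", {
  set.seed(92)
  short <- simulate_sequence(0.5, 0.4, rep("DAY", 1e5))
  long <- simulate_sequence(0.02, 0.4, rep("DAY", 1e5))
  s <- encoded_sequence(c(short$states, long$states), rep("DAY", 2e5))
  fit <- suppressWarnings(fit_markov(s))
  b <- extract_bouts(s)
  tab <- bout_distribution_comparison(b, fit, "DAY", "R")
  # single-parameter fit underestimates the very short and very long bouts
  expect_gt(tab$observed[1], tab$predicted[1])
  k_tail <- tab$length_bins > 3 / fit$alpha[["DAY"]]
  expect_gt(sum(tab$observed[k_tail]), sum(tab$predicted[k_tail]))
})

test_that("distribution tables handle sparse and absent bouts", {
  s <- encoded_sequence(c("A", "R", "R", "R", "A"), rep("DAY", 5))
  fit <- suppressWarnings(fit_markov(s))
  b <- extract_bouts(s)
  tab <- bout_distribution_comparison(b, fit, "DAY", "R")
  expect_identical(attr(tab, "n_bouts"), 1L)
  expect_equal(tab$observed[3], 1)

  none <- bout_distribution_comparison(b, fit, "NIGHT", "A")
  expect_identical(nrow(none), 0L)
  expect_identical(attr(none, "n_bouts"), 0L)
})

test_that("the distribution check has power against a wrong parameter", {
  set.seed(93)
  alpha <- 0.1
  s <- simulate_sequence(alpha, 0.4, rep("DAY", 3e5))
  b <- extract_bouts(s)
  lens <- b$length_bins[b$state == "R" & !b$truncated]
  kmax <- 40
  obs <- tabulate(pmin(lens, kmax), nbins = kmax)
  gof_p <- function(p0) {
    pr <- c(geometric_bout_pmf(p0, 1:(kmax - 1)), (1 - p0)^(kmax - 1))
    suppressWarnings(stats::chisq.test(obs, p = pr)$p.value)
  }
  expect_gt(gof_p(alpha), 0.01)
  expect_lt(gof_p(alpha * 1.5), 1e-6)
  expect_lt(gof_p(alpha * 0.5), 1e-6)
})
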