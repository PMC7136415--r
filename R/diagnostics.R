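#' Split-half stability of the transition-probability estimates
#'
#' Fits the Markov model independently to the first and second halves of a
#' record (split at the midpoint bin). Under stationarity, the two halves
#' should agree; a drifting or regime-switching animal shows up as a
#' systematic difference.
#'
#' @param seq an `encoded_sequence`.
#' @return A list of class `split_half` with elements `first` and `second`
#'   (two `markov_fit`s) and `comparison`, a data frame of paired
#'   parameter estimates (phase x parameter).
#' @seealso [split_half_correlation()] for the cohort-level summary.
#' @export
split_half_stability <- function(seq) {
  stopifnot(inherits(seq, "encoded_sequence"))
  if (seq$n_bins < 2L)
    stop("need at least two bins to split in half", call. = FALSE)
  mid <- seq$n_bins %/% 2L
  take <- function(idx) {
    g <- seq$gaps[seq$gaps >= idx[1L] & seq$gaps < idx[length(idx)]]
    encoded_sequence(seq$states[idx], seq$phase[idx],
                     bin_seconds = seq$bin_seconds,
                     animal_id = seq$animal_id, gaps = g - idx[1L] + 1L)
  }
  # a half too short to hold a transition yields an all-NaN fit (with a
  # warning), mirroring the undefined-estimate contract of fit_markov
  safe_fit <- function(idx) {
    if (length(idx) < 2L) {
      warning(warningCondition(
        "half-record too short to estimate transitions; estimates are NaN",
        class = "actimark_undefined_estimate"))
      return(fit_markov(structure(
        matrix(0L, 2L, 4L,
               dimnames = list(c("DAY", "NIGHT"), c("RR", "RA", "AR", "AA"))),
        class = c("transition_counts", "matrix")),
        bin_seconds = seq$bin_seconds))
    }
    fit_markov(take(idx))
  }
  f1 <- safe_fit(1:mid)
  f2 <- safe_fit((mid + 1L):seq$n_bins)
  comparison <- data.frame(
    parameter = rep(c("alpha", "beta"), each = 2L),
    phase = rep(c("DAY", "NIGHT"), 2L),
    first_half = c(f1$alpha, f1$beta),
    second_half = c(f2$alpha, f2$beta))
  structure(list(first = f1, second = f2, comparison = comparison),
            class = "split_half")
}

#' @export
print.split_half <- function(x, ...) {
  cat("Split-half stability of Markov estimates\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Across-animal correlation of split-half estimates
#'
#' Runs [split_half_stability()] on every animal of a cohort and
#' correlates first-half against second-half estimates across animals and
#' phases — the cohort-level stationarity summary (Pearson r, separately
#' for alpha and beta).
#'
#' @param seqs a list of `encoded_sequence`s, or a `cohort`.
#' @return List with `r_alpha`, `r_beta` and the pooled `table` of paired
#'   estimates.
#' @export
split_half_correlation <- function(seqs) {
  if (inherits(seqs, "cohort")) seqs <- seqs$sequences
  tabs <- lapply(seqs, function(s) {
    sh <- split_half_stability(s)
    cbind(sh$comparison, animal_id = s$animal_id)
  })
  tab <- do.call(rbind, tabs)
  ok <- stats::complete.cases(tab[, c("first_half", "second_half")])
  cor_par <- function(p) {
    sub <- tab[ok & tab$parameter == p, ]
    if (nrow(sub) < 3L) return(NA_real_)
    stats::cor(sub$first_half, sub$second_half)
  }
  list(r_alpha = cor_par("alpha"), r_beta = cor_par("beta"), table = tab)
}

#' Conditional mutual information test of the Markov property
#'
#' Plug-in estimate of `I(S[n+1]; S[n-1] | S[n])` in bits from the
#' empirical frequencies of state triples (triples spanning a recording
#' gap are excluded). For a first-order Markov chain the future is
#' independent of the past given the present, so the conditional mutual
#' information is zero up to estimation noise; values well above zero
#' indicate higher-order structure. Zero-count cells contribute zero.
#'
#' @param seq an `encoded_sequence` with at least three bins.
#' @param by_phase if `TRUE`, also return the estimate computed within each
#'   phase (conditioning triples on the phase of the middle bin).
#' @return Conditional mutual information in bits (non-negative), or when
#'   `by_phase = TRUE` a list with `overall` and `by_phase` elements.
#' @export
#' @examples
#' s <- simulate_sequence(0.2, 0.4, rep("DAY", 5000), seed = 1)
#' conditional_mutual_information(s)  # near zero by construction
conditional_mutual_information <- function(seq, by_phase = FALSE) {
  stopifnot(inherits(seq, "encoded_sequence"))
  n <- seq$n_bins
  if (n < 3L) stop("need at least three bins", call. = FALSE)
  i <- 2:(n - 1L)  # middle bin of each triple
  if (length(seq$gaps))
    i <- i[!((i - 1L) %in% seq$gaps) & !(i %in% seq$gaps)]
  if (!length(i)) stop("no gap-free triples available", call. = FALSE)
  past <- seq$states[i - 1L]
  pres <- seq$states[i]
  futr <- seq$states[i + 1L]

  overall <- cmi_from_triples(past, pres, futr)
  if (!by_phase) return(overall)
  ph <- seq$phase[i]
  by_ph <- vapply(c(DAY = "DAY", NIGHT = "NIGHT"), function(p) {
    k <- ph == p
    if (sum(k) < 2L) return(NA_real_)
    cmi_from_triples(past[k], pres[k], futr[k])
  }, numeric(1))
  list(overall = overall, by_phase = by_ph)
}

cmi_from_triples <- function(past, pres, futr) {
  lv <- c("R", "A")
  tab <- table(factor(past, lv), factor(pres, lv), factor(futr, lv))
  p3 <- tab / sum(tab)
  p_pres <- apply(p3, 2L, sum)
  p_pp <- apply(p3, c(1L, 2L), sum)  # (past, present)
  p_pf <- apply(p3, c(2L, 3L), sum)  # (present, future)
  cmi <- 0
  for (a in 1:2) for (s in 1:2) for (b in 1:2) {
    p <- p3[a, s, b]
    if (p > 0)
      cmi <- cmi + p * log2(p * p_pres[s] / (p_pp[a, s] * p_pf[s, b]))
  }
  max(cmi, 0)
}

#' Observed versus model-predicted bout-length distribution
#'
#' Compares the empirical distribution of bout lengths for one state in
#' one phase against the geometric distribution implied by the fitted exit
#' probability (`alpha` for rest bouts, `beta` for activity bouts).
#' Truncated bouts are excluded from the observed histogram by default
#' because censoring biases their lengths. The table covers lengths 1 to
#' the maximum observed; the model's tail mass beyond that is reported as
#' an attribute so both columns account for all probability.
#'
#' @param bouts a `bout_table` from [extract_bouts()].
#' @param fit a `markov_fit`.
#' @param phase `"DAY"` or `"NIGHT"`.
#' @param state `"R"` or `"A"`.
#' @param include_truncated include censored bouts in the histogram.
#' @return A data frame of class `bout_distribution` with columns
#'   `length_bins`, `observed` and `predicted` (both probability
#'   distributions over the shown support; attribute `tail_mass` holds the
#'   predicted mass beyond the longest observed bout, attribute `n_bouts`
#'   the number of bouts used). If no qualifying bouts exist, a zero-row
#'   sentinel with `n_bouts = 0`.
#' @export
bout_distribution_comparison <- function(bouts, fit, phase, state,
                                         include_truncated = FALSE) {
  stopifnot(inherits(fit, "markov_fit"))
  phase <- match.arg(phase, c("DAY", "NIGHT"))
  state <- match.arg(state, c("R", "A"))
  keep <- bouts$phase == phase & bouts$state == state
  if (!include_truncated) keep <- keep & !bouts$truncated
  lens <- bouts$length_bins[keep]
  empty <- data.frame(length_bins = integer(0), observed = numeric(0),
                      predicted = numeric(0))
  if (!length(lens)) {
    return(structure(empty, class = c("bout_distribution", "data.frame"),
                     tail_mass = NA_real_, n_bouts = 0L))
  }
  prob <- if (state == "R") fit$alpha[[phase]] else fit$beta[[phase]]
  if (!is.finite(prob) || prob <= 0) {
    warning("exit probability for ", state, "/", phase,
            " is undefined; returning observed histogram only")
    prob <- NA_real_
  }
  kmax <- max(lens)
  k <- seq_len(kmax)
  obs <- tabulate(lens, nbins = kmax) / length(lens)
  pred <- if (is.na(prob)) rep(NA_real_, kmax) else geometric_bout_pmf(prob, k)
  tail_mass <- if (is.na(prob)) NA_real_ else (1 - prob)^kmax
  structure(data.frame(length_bins = k, observed = obs, predicted = pred),
            class = c("bout_distribution", "data.frame"),
            tail_mass = tail_mass, n_bouts = length(lens),
            phase = phase, state = state)
}

#' Plot a fitted model's bout-length distributions
#'
#' Draws, for each phase and state, the observed bout-length histogram
#' (solid) against the model's geometric prediction (dashed) on a
#' log-scaled length axis, the standard way these distributions are
#' inspected (short bouts dominate; deviations live in the tails).
#'
#' @param x a `markov_fit`.
#' @param bouts a `bout_table` from the same record.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.markov_fit <- function(x, bouts, ...) {
  if (missing(bouts))
    stop("supply the bout table of the fitted record", call. = FALSE)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ph in c("DAY", "NIGHT")) for (st in c("R", "A")) {
    d <- bout_distribution_comparison(bouts, x, ph, st)
    if (nrow(d) == 0) {
      graphics::plot.new()
      graphics::title(main = sprintf("%s bouts, %s (none)", st, ph))
      next
    }
    graphics::matplot(d$length_bins,
                      cbind(d$observed, d$predicted),
                      type = "l", lty = c(1, 2), col = c("black", "red"),
                      log = "x", xlab = "bout length (bins)",
                      ylab = "probability",
                      main = sprintf("%s bouts, %s", st, ph), ...)
  }
  invisible(x)
}
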