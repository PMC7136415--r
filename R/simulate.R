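#' Simulate a rest/activity sequence from the Markov model
#'
#' Generates one encoded sequence by running the two-state chain forward:
#' the first bin is drawn according to `initial_state` (for
#' `"STATIONARY"`, active with probability `alpha/(alpha + beta)` of the
#' first bin's phase — the chain's stationary activity fraction), and each
#' subsequent bin switches state with the current phase's transition
#' probability (`alpha` out of rest, `beta` out of activity). Identical
#' inputs and seed give an identical sequence.
#'
#' @param alpha,beta transition probabilities; either single numbers (used
#'   in both phases) or named vectors with elements `DAY` and `NIGHT`.
#' @param phase character vector of `"DAY"`/`"NIGHT"` labels, one per
#'   simulated bin; its length sets the sequence length.
#' @param bin_seconds bin width in seconds.
#' @param initial_state `"STATIONARY"`, `"A"` or `"R"`.
#' @param animal_id identifier for the simulated record.
#' @param seed optional integer; when supplied, the RNG state is set
#'   locally and restored afterwards.
#' @return An `encoded_sequence`.
#' @export
#' @examples
#' s <- simulate_sequence(alpha = 0.1, beta = 0.3,
#'                        phase = rep("NIGHT", 1000), seed = 1)
#' mean(s$states == "A")  # ~ 0.1 / 0.4
simulate_sequence <- function(alpha, beta, phase, bin_seconds = 10L,
                              initial_state = c("STATIONARY", "A", "R"),
                              animal_id = "sim", seed = NULL) {
  initial_state <- match.arg(initial_state)
  phase <- as.character(phase)
  n <- length(phase)
  if (n < 1L) stop("phase must supply at least one bin", call. = FALSE)
  if (!all(phase %in% c("DAY", "NIGHT")))
    stop("phase labels must be \"DAY\" or \"NIGHT\"", call. = FALSE)
  alpha <- expand_phase_param(alpha, "alpha")
  beta <- expand_phase_param(beta, "beta")

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }

  a_vec <- alpha[phase]
  b_vec <- beta[phase]
  u <- stats::runif(n)
  active <- logical(n)
  active[1L] <- switch(initial_state,
    A = TRUE, R = FALSE,
    STATIONARY = {
      tot <- a_vec[1L] + b_vec[1L]
      if (tot == 0)
        stop("stationary initial state is undefined when alpha + beta = 0",
             call. = FALSE)
      u[1L] < a_vec[1L] / tot
    })
  if (n > 1L) {
    s <- active[1L]
    for (i in 2L:n) {
      s <- if (s) u[i] >= b_vec[i - 1L] else u[i] < a_vec[i - 1L]
      active[i] <- s
    }
  }
  encoded_sequence(states = ifelse(active, "A", "R"), phase = phase,
                   bin_seconds = bin_seconds, animal_id = animal_id)
}

expand_phase_param <- function(p, name) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop(name, " must be probabilities in [0, 1]", call. = FALSE)
  if (length(p) == 1L) return(c(DAY = p, NIGHT = p))
  if (!all(c("DAY", "NIGHT") %in% names(p)))
    stop(name, " must be a single number or a named vector with DAY and ",
         "NIGHT elements", call. = FALSE)
  p[c("DAY", "NIGHT")]
}

#' Simulate sequences from a fitted Markov model
#'
#' Draws `nsim` independent sequences from the fitted phase-conditional
#' transition probabilities — the generative use of the model (e.g. to
#' build a surrogate cohort matched to the original recordings for
#' periodogram analysis).
#'
#' @param object a `markov_fit`.
#' @param nsim number of sequences.
#' @param seed optional integer seed (RNG state restored afterwards, as
#'   with other `simulate()` methods).
#' @param phase per-bin phase labels for the simulated record (required).
#' @param initial_state see [simulate_sequence()].
#' @param ... unused.
#' @return An `encoded_sequence` if `nsim = 1`, otherwise a list of them.
#' @export
simulate.markov_fit <- function(object, nsim = 1, seed = NULL, phase,
                                initial_state = "STATIONARY", ...) {
  if (missing(phase))
    stop("supply per-bin phase labels via the phase argument", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  if (any(!is.finite(object$alpha)) || any(!is.finite(object$beta)))
    stop("cannot simulate from a fit with undefined (NaN) parameters",
         call. = FALSE)
  out <- lapply(seq_len(nsim), function(k)
    simulate_sequence(object$alpha, object$beta, phase,
                      bin_seconds = object$bin_seconds,
                      initial_state = initial_state,
                      animal_id = paste0(object$animal_id, "_sim", k)))
  if (nsim == 1L) out[[1L]] else out
}

#' Phase label track for a housing condition
#'
#' Builds the per-bin `"DAY"`/`"NIGHT"` track used to drive simulations:
#' under a T-cycle, lights on (DAY) for the first half of every cycle of
#' `period_h` hours starting at time zero; under constant darkness the same
#' tiling with the animal's free-running period, with subjective NIGHT
#' (the active phase) first, matching activity onset at the start of the
#' subjective night.
#'
#' @param n_bins number of bins.
#' @param period_h cycle period in hours.
#' @param bin_seconds bin width in seconds.
#' @param night_first logical; if `TRUE` the cycle starts with NIGHT.
#' @return Character vector of labels.
#' @export
phase_track <- function(n_bins, period_h, bin_seconds = 10L,
                        night_first = FALSE) {
  t <- (seq_len(n_bins) - 1L) * bin_seconds / 3600
  first_half <- (t %% period_h) < period_h / 2
  if (night_first) ifelse(first_half, "NIGHT", "DAY")
  else ifelse(first_half, "DAY", "NIGHT")
}

#' Simulate a cohort of animals
#'
#' Generates a cohort with the statistical structure the analysis assumes:
#' each animal's transition probabilities are drawn lognormally around the
#' cohort means with coefficient of variation `inter_animal_cv`
#' (mean-preserving parameterisation), its phase track follows the housing
#' condition (equal light and dark halves at the T-cycle period, or the
#' animal's own free-running period under DD), and its states are simulated
#' with [simulate_sequence()]. The generating truth is returned alongside
#' the data so that estimator-recovery can be tested. Identical arguments
#' and seed reproduce the cohort bit for bit.
#'
#' Defaults emulate the study design: cohort sizes 8/16/8 for the 22-, 24-
#' and 26-h T-cycles and 16 for DD; 7 recorded days (comfortably above the
#' four-cycle inclusion rule); 10-s bins; cohort-mean parameters from the
#' published bout lengths ([default_markov_params()]); 20% inter-animal
#' coefficient of variation; DD free-running periods near 23.8 h.
#'
#' @param condition one of `"LD22"`, `"LD24"`, `"LD26"`, `"DD"`.
#' @param n_animals cohort size; default is the study composition for the
#'   condition (8, 16, 8, 16 respectively).
#' @param record_days recording length in 24-h days.
#' @param bin_seconds bin width in seconds.
#' @param params named list `alpha_day`, `beta_day`, `alpha_night`,
#'   `beta_night` of cohort-mean transition probabilities.
#' @param inter_animal_cv lognormal coefficient of variation of the
#'   per-animal parameters (0 = identical animals).
#' @param dd_period_h cohort-mean free-running period in hours (DD only).
#' @param dd_period_jitter_h SD of the per-animal normal jitter on the
#'   free-running period, truncated to `[20, 28]` h (DD only).
#' @param initial_state see [simulate_sequence()].
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @param animal_prefix prefix for generated animal ids.
#' @return An object of class `cohort`: list with `sequences` (list of
#'   `encoded_sequence`), `truth` (data frame of per-animal generating
#'   parameters) and `config` (the arguments).
#' @export
#' @examples
#' coh <- simulate_cohort("LD24", n_animals = 2, record_days = 4, seed = 1)
#' coh$truth
simulate_cohort <- function(condition, n_animals = NULL, record_days = 7,
                            bin_seconds = 10L,
                            params = default_markov_params(condition, bin_seconds),
                            inter_animal_cv = 0.2,
                            dd_period_h = 23.8, dd_period_jitter_h = 0.2,
                            initial_state = "STATIONARY", seed = NULL,
                            animal_prefix = NULL) {
  condition <- match.arg(condition, c("LD22", "LD24", "LD26", "DD"))
  if (is.null(n_animals))
    n_animals <- switch(condition, LD22 = 8L, LD24 = 16L, LD26 = 8L, DD = 16L)
  if (n_animals < 1L) stop("n_animals must be >= 1", call. = FALSE)
  if (inter_animal_cv < 0) stop("inter_animal_cv must be >= 0", call. = FALSE)
  pm <- unlist(params[c("alpha_day", "beta_day", "alpha_night", "beta_night")])
  if (any(is.na(pm)) || any(pm <= 0) || any(pm >= 1))
    stop("cohort-mean probabilities must lie strictly in (0, 1)",
         call. = FALSE)
  base_period <- if (condition == "DD") dd_period_h else condition_period(condition)
  if (record_days * 24 < 4 * base_period)
    stop(sprintf("record_days = %.2f gives fewer than the four cycles of %g h
required for inclusion", record_days, base_period), call. = FALSE)
  if (is.null(animal_prefix)) animal_prefix <- tolower(condition)

  if (!is.null(seed)) set.seed(seed)
  n_bins <- round(record_days * 86400 / bin_seconds)

  # mean-preserving lognormal heterogeneity on each parameter independently
  draw <- function(m) {
    if (inter_animal_cv == 0) return(rep(m, n_animals))
    sdlog <- sqrt(log(1 + inter_animal_cv^2))
    pmin(pmax(stats::rlnorm(n_animals, log(m) - sdlog^2 / 2, sdlog),
              1e-6), 1 - 1e-6)
  }
  truth <- data.frame(
    animal_id = sprintf("%s_%02d", animal_prefix, seq_len(n_animals)),
    condition = condition,
    alpha_day = draw(pm[["alpha_day"]]),
    beta_day = draw(pm[["beta_day"]]),
    alpha_night = draw(pm[["alpha_night"]]),
    beta_night = draw(pm[["beta_night"]]))
  if (condition == "DD") {
    truth$period_h <- pmin(pmax(
      stats::rnorm(n_animals, dd_period_h, dd_period_jitter_h), 20), 28)
  } else {
    truth$period_h <- base_period
  }

  sequences <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    ph <- phase_track(n_bins, truth$period_h[i], bin_seconds,
                      night_first = condition == "DD")
    sequences[[i]] <- simulate_sequence(
      alpha = c(DAY = truth$alpha_day[i], NIGHT = truth$alpha_night[i]),
      beta = c(DAY = truth$beta_day[i], NIGHT = truth$beta_night[i]),
      phase = ph, bin_seconds = bin_seconds, initial_state = initial_state,
      animal_id = truth$animal_id[i])
  }
  names(sequences) <- truth$animal_id

  structure(list(sequences = sequences, truth = truth,
                 config = list(condition = condition, n_animals = n_animals,
                               record_days = record_days,
                               bin_seconds = bin_seconds, params = params,
                               inter_animal_cv = inter_animal_cv,
                               dd_period_h = dd_period_h,
                               dd_period_jitter_h = dd_period_jitter_h,
                               initial_state = initial_state, seed = seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d %s animals, %g days of %g-s bins\n",
              x$config$n_animals, x$config$condition, x$config$record_days,
              x$config$bin_seconds))
  invisible(x)
}
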