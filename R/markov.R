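#' Count phase-conditional state transitions
#'
#' Tabulates the transitions between adjacent bins of an encoded sequence,
#' conditioned on the circadian phase. Each adjacent pair `(n, n + 1)` that
#' does not span a recording gap contributes one count to the cell indexed
#' by the ordered state pair under the phase of bin `n` (the conditioning
#' variable of the estimator); pairs across gaps are dropped so that
#' missing stretches never masquerade as transitions.
#'
#' @param seq an `encoded_sequence` with at least two bins.
#' @return A `transition_counts` object: a 2 x 4 integer matrix with rows
#'   `DAY`, `NIGHT` and columns `RR`, `RA`, `AR`, `AA` (`RA` meaning rest
#'   followed by activity, and so on).
#' @export
#' @examples
#' s <- encoded_sequence(c("R", "R", "A", "A", "R", "A"), rep("DAY", 6))
#' count_transitions(s)
count_transitions <- function(seq) {
  stopifnot(inherits(seq, "encoded_sequence"))
  n <- seq$n_bins
  if (n < 2L)
    stop("need at least two bins to count transitions", call. = FALSE)
  i <- seq_len(n - 1L)
  if (length(seq$gaps)) i <- i[!(i %in% seq$gaps)]
  pair <- paste0(seq$states[i], seq$states[i + 1L])
  ph <- seq$phase[i]
  m <- matrix(0L, nrow = 2L, ncol = 4L,
              dimnames = list(c("DAY", "NIGHT"), c("RR", "RA", "AR", "AA")))
  tab <- table(factor(ph, levels = c("DAY", "NIGHT")),
               factor(pair, levels = c("RR", "RA", "AR", "AA")))
  m[] <- as.integer(tab)
  structure(m, class = c("transition_counts", class(m)))
}

#' Fit the two-state Markov model of rest and activity
#'
#' The behavioral state in the next bin is assumed to depend only on the
#' current state and the circadian phase: from rest the animal becomes
#' active with probability `alpha(X)`, from activity it returns to rest
#' with probability `beta(X)`, with a separate parameter pair for day and
#' night (`X`). The maximum-likelihood estimates are the observed
#' conditional transition frequencies
#' \deqn{\hat\alpha(X) = n_{RA}(X) / (n_{RA}(X) + n_{RR}(X)), \quad
#'       \hat\beta(X) = n_{AR}(X) / (n_{AR}(X) + n_{AA}(X)).}
#'
#' Under the model, bout lengths are geometric, so the mean rest and
#' activity bout lengths are `1/alpha` and `1/beta` bins — with 10-s bins,
#' `1/(6 alpha)` and `1/(6 beta)` minutes — and the long-run fraction of
#' time spent active in a phase is `alpha / (alpha + beta)`.
#'
#' A phase in which a state is never observed has an undefined estimate:
#' the corresponding entries are `NaN` and a warning of class
#' `actimark_undefined_estimate` is signalled, never a silent zero.
#'
#' @param x an `encoded_sequence`, or a `transition_counts` matrix from
#'   [count_transitions()].
#' @param bin_seconds bin width in seconds; taken from the sequence when
#'   `x` is an `encoded_sequence`.
#' @return An object of class `markov_fit` with components `alpha`, `beta`
#'   (named numeric, `DAY`/`NIGHT`), `counts`, `bin_seconds`,
#'   `mean_rest_bout_min`, `mean_activity_bout_min`, `average_activity`
#'   and `animal_id`. Supports [coef()], [summary()], [simulate()] and
#'   [plot()].
#' @seealso [simulate.markov_fit()], [bout_distribution_comparison()]
#' @export
#' @examples
#' s <- encoded_sequence(c("R", "R", "A", "A", "R", "A"), rep("DAY", 6))
#' fit <- fit_markov(s)
#' coef(fit)
fit_markov <- function(x, bin_seconds = 10L) {
  animal_id <- NA_character_
  if (inherits(x, "encoded_sequence")) {
    bin_seconds <- x$bin_seconds
    animal_id <- x$animal_id
    counts <- count_transitions(x)
  } else if (inherits(x, "transition_counts")) {
    counts <- x
  } else {
    stop("x must be an encoded_sequence or transition_counts", call. = FALSE)
  }

  den_a <- counts[, "RA"] + counts[, "RR"]
  den_b <- counts[, "AR"] + counts[, "AA"]
  alpha <- ifelse(den_a > 0, counts[, "RA"] / den_a, NaN)
  beta <- ifelse(den_b > 0, counts[, "AR"] / den_b, NaN)
  names(alpha) <- names(beta) <- rownames(counts)
  undef <- c(names(alpha)[den_a == 0], names(beta)[den_b == 0])
  if (length(undef))
    warning(warningCondition(
      paste0("no observed transitions for phase(s) ",
             paste(unique(undef), collapse = ", "),
             "; the corresponding estimates are undefined (NaN)"),
      class = "actimark_undefined_estimate"))

  structure(
    list(alpha = alpha, beta = beta, counts = counts,
         bin_seconds = bin_seconds,
         mean_rest_bout_min = bin_seconds / (60 * alpha),
         mean_activity_bout_min = bin_seconds / (60 * beta),
         average_activity = alpha / (alpha + beta),
         animal_id = animal_id),
    class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, digits = 4, ...) {
  cat("Two-state Markov model of rest/activity")
  if (!is.na(x$animal_id)) cat(" --", x$animal_id)
  cat("\n\n")
  print(round(rbind(`alpha (R->A)` = x$alpha,
                    `beta  (A->R)` = x$beta,
                    `mean rest bout (min)` = x$mean_rest_bout_min,
                    `mean activity bout (min)` = x$mean_activity_bout_min,
                    `average activity` = x$average_activity), digits))
  invisible(x)
}

#' @export
coef.markov_fit <- function(object, ...) {
  cbind(alpha = object$alpha, beta = object$beta)
}

#' @export
summary.markov_fit <- function(object, ...) {
  structure(list(fit = object,
                 n_pairs = rowSums(object$counts),
                 counts = object$counts),
            class = "summary.markov_fit")
}

#' @export
print.summary.markov_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTransition counts (rows: phase of the origin bin):\n")
  print(x$counts)
  cat("\nAdjacent bin pairs per phase:",
      paste(names(x$n_pairs), x$n_pairs, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Geometric bout-length distribution implied by the model
#'
#' Under the Markov model a bout of a given state ends each bin with the
#' state's exit probability `prob` (`alpha` for rest, `beta` for
#' activity), so bout lengths follow the geometric distribution
#' `P(K = k) = (1 - prob)^(k - 1) prob` on `k = 1, 2, ...` bins with mean
#' `1 / prob` bins.
#'
#' @param prob per-bin exit probability, in `(0, 1]`.
#' @param k bout length(s) in bins, integer `>= 1`.
#' @return `P(K = k)` for each `k`.
#' @export
geometric_bout_pmf <- function(prob, k) {
  if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
      prob <= 0 || prob > 1)
    stop("prob must be a single probability in (0, 1]", call. = FALSE)
  if (any(k < 1) || any(k != floor(k)))
    stop("bout lengths must be integers >= 1", call. = FALSE)
  (1 - prob)^(k - 1) * prob
}

#' Convert mean bout lengths to per-bin transition probabilities
#'
#' Inverts the model's mean-bout relation: a mean rest bout of `m` minutes
#' at `bin_seconds`-second bins corresponds to
#' `alpha = bin_seconds / (60 m)` (and likewise `beta` from the mean
#' activity bout). With the study's 10-s bins this is the familiar
#' `1/(6 alpha)`-minute rule.
#'
#' @param activity_min mean activity bout length in minutes.
#' @param rest_min mean rest bout length in minutes.
#' @param bin_seconds bin width in seconds.
#' @return Named list with elements `alpha` and `beta`.
#' @export
#' @examples
#' bout_means_to_rates(activity_min = 0.75, rest_min = 1.75)
bout_means_to_rates <- function(activity_min, rest_min, bin_seconds = 10L) {
  if (any(activity_min <= 0) || any(rest_min <= 0))
    stop("mean bout lengths must be positive", call. = FALSE)
  list(alpha = bin_seconds / (60 * rest_min),
       beta = bin_seconds / (60 * activity_min))
}

#' Published reference mean bout lengths
#'
#' Cohort-mean rest and activity bout lengths (minutes) reported for
#' C57BL/6 mice under entrained light-dark T-cycles (`LD`, pooled over the
#' 22-, 24- and 26-h cycles) and under constant darkness (`DD`, subjective
#' phases). These serve as the default generating parameters of
#' [simulate_cohort()] and as reference inputs for consistency checks;
#' they convert to transition probabilities via [bout_means_to_rates()].
#'
#' @return A data frame with columns `condition` (`"LD"`/`"DD"`), `phase`
#'   (`"DAY"`/`"NIGHT"`), `activity_min` and `rest_min`.
#' @export
reference_bout_minutes <- function() {
  data.frame(
    condition = c("LD", "LD", "DD", "DD"),
    phase = c("NIGHT", "DAY", "NIGHT", "DAY"),
    activity_min = c(0.75, 0.54, 0.67, 0.55),
    rest_min = c(1.75, 4.50, 2.68, 4.05))
}

#' Default generating transition probabilities for a housing condition
#'
#' Looks up the published mean bout lengths ([reference_bout_minutes()])
#' for the LD (any T-cycle) or DD condition and converts them to the
#' per-phase transition probabilities `alpha` and `beta`.
#'
#' @param condition one of `"LD22"`, `"LD24"`, `"LD26"`, `"DD"`.
#' @param bin_seconds bin width in seconds.
#' @return Named list `alpha_day`, `beta_day`, `alpha_night`, `beta_night`.
#' @export
default_markov_params <- function(condition, bin_seconds = 10L) {
  condition <- match.arg(condition, c("LD22", "LD24", "LD26", "DD"))
  grp <- if (condition == "DD") "DD" else "LD"
  ref <- reference_bout_minutes()
  day <- ref[ref$condition == grp & ref$phase == "DAY", ]
  night <- ref[ref$condition == grp & ref$phase == "NIGHT", ]
  rd <- bout_means_to_rates(day$activity_min, day$rest_min, bin_seconds)
  rn <- bout_means_to_rates(night$activity_min, night$rest_min, bin_seconds)
  list(alpha_day = rd$alpha, beta_day = rd$beta,
       alpha_night = rn$alpha, beta_night = rn$beta)
}
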