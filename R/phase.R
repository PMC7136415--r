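#' Per-bin circadian phase assignment
#'
#' A `phase_assignment` holds one `"DAY"`/`"NIGHT"` label per bin together
#' with how it was obtained: directly from the light flags of a T-cycle
#' record (`LIGHT_FLAGS`), or from a cosinor fit of the free-running
#' rhythm for constant-darkness records (`COSINE_FIT`, see
#' [fit_cosine_phase()]).
#'
#' @name phase_assignment
#' @keywords internal
NULL

new_phase_assignment <- function(labels, method, period_h,
                                 acrophase_h = NA_real_,
                                 fit_quality = NA_real_) {
  structure(list(labels = labels, method = method, period_h = period_h,
                 acrophase_h = acrophase_h, fit_quality = fit_quality),
            class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat("Phase assignment (", x$method, ")\n", sep = "")
  cat(sprintf("  period %.2f h; %d DAY / %d NIGHT bins\n", x$period_h,
              sum(x$labels == "DAY"), sum(x$labels == "NIGHT")))
  if (x$method == "COSINE_FIT")
    cat(sprintf("  acrophase %.2f h after record start; R^2 = %.3f\n",
                x$acrophase_h, x$fit_quality))
  invisible(x)
}

#' Label day and night from the light flags of a T-cycle record
#'
#' Under entrained light-dark housing the circadian phase is read directly
#' off the recorded flags: `DAY` wherever lights were on (`"L"`), `NIGHT`
#' wherever off (`"D"`). The assignment's period is the nominal T-cycle
#' period.
#'
#' @param record an [activity_record()] from an LD condition.
#' @return A `phase_assignment` with method `LIGHT_FLAGS`.
#' @export
label_from_light <- function(record) {
  stopifnot(inherits(record, "activity_record"))
  if (any(is.na(record$light)))
    stop("record carries no light flags; use fit_cosine_phase() for ",
         "constant-darkness records", call. = FALSE)
  new_phase_assignment(labels = ifelse(record$light == "L", "DAY", "NIGHT"),
                       method = "LIGHT_FLAGS",
                       period_h = condition_period(record$condition))
}

#' Label subjective day and night by cosinor fitting
#'
#' For constant-darkness records the circadian phase must be inferred from
#' the behavior itself. A cosine curve is fitted to the raw activity counts
#' at each candidate period on a grid (exact linear least squares of
#' `mean + a cos + b sin` per period — the cosinor parameterisation); the
#' free-running period tau is the grid period with the largest variance
#' explained. The acrophase is the peak time of the fitted cosine, in hours
#' after the record start. Mice are nocturnal, so subjective `NIGHT` is the
#' half-period window centred on the acrophase, tiled periodically;
#' the other half-cycle is subjective `DAY`.
#'
#' @param record an [activity_record()] spanning at least four cycles of
#'   the longest candidate period (the study's inclusion rule).
#' @param period_min,period_max,period_step candidate-period grid in hours.
#'   The default 20-28 h brackets murine free-running periods.
#' @return A `phase_assignment` with method `COSINE_FIT`; `period_h` is the
#'   fitted tau, `fit_quality` the coefficient of determination of the
#'   winning cosinor fit.
#' @export
#' @examples
#' set.seed(1)
#' t_h <- (0:(8 * 8640 - 1)) / 360          # 8 days of 10-s bins
#' lam <- pmax(0, cos(2 * pi * t_h / 23.6)) # rectified cosine drive
#' rec <- activity_record(rpois(length(t_h), 2 * lam), condition = "DD")
#' ph <- fit_cosine_phase(rec)
#' ph$period_h
fit_cosine_phase <- function(record, period_min = 20, period_max = 28,
                             period_step = 0.1) {
  stopifnot(inherits(record, "activity_record"))
  if (period_min <= 0 || period_max <= period_min)
    stop("invalid period grid", call. = FALSE)
  t <- record$time_h - record$time_h[1L]
  span <- t[length(t)] - t[1L] + record$bin_seconds / 3600
  if (span < 4 * period_max)
    stop(sprintf(paste0("record spans %.1f h but the inclusion rule requires ",
                        "at least four cycles of the longest candidate ",
                        "period (%.0f h)"), span, 4 * period_max),
         call. = FALSE)
  y <- as.numeric(record$counts)
  if (all(y == 0))
    stop("all activity counts are zero; cosinor fit is degenerate",
         call. = FALSE)
  tss <- sum((y - mean(y))^2)
  if (tss == 0)
    stop("activity counts are constant; cosinor fit is degenerate ",
         "(zero amplitude)", call. = FALSE)

  periods <- seq(period_min, period_max, by = period_step)
  best <- list(r2 = -Inf)
  for (P in periods) {
    w <- 2 * pi * t / P
    X <- cbind(1, cos(w), sin(w))
    f <- stats::lm.fit(X, y)
    r2 <- 1 - sum(f$residuals^2) / tss
    if (r2 > best$r2)
      best <- list(r2 = r2, P = P, a = f$coefficients[2L],
                   b = f$coefficients[3L])
  }
  amp <- sqrt(best$a^2 + best$b^2)
  if (!is.finite(amp) || amp < 1e-10 * max(1, mean(y)))
    stop("fitted cosine has (near-)zero amplitude; cannot define phases",
         call. = FALSE)
  # mean + a cos(wt) + b sin(wt) = mean + amp * cos(wt - phi), peak at phi/w
  acro <- (atan2(best$b, best$a) / (2 * pi) * best$P) %% best$P
  # circular distance of each bin from the acrophase; NIGHT within P/4 of it
  d <- abs((t - acro + best$P / 2) %% best$P - best$P / 2)
  new_phase_assignment(labels = ifelse(d < best$P / 4, "NIGHT", "DAY"),
                       method = "COSINE_FIT", period_h = best$P,
                       acrophase_h = acro, fit_quality = best$r2)
}
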