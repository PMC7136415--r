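#' Cohort-level summary of fitted Markov models
#'
#' Aggregates per-animal model summaries (average activity, mean rest and
#' activity bout lengths, total bouts per phase) into cohort estimates.
#' Ratios and fold changes are multiplicative quantities, so each
#' within-animal day/night fold and rest/activity ratio is averaged on the
#' log scale (geometric mean) and back-transformed; 95% confidence
#' intervals come from an animal-level nonparametric bootstrap (resampling
#' animals with replacement). Animals with undefined entries for a
#' quantity are excluded from that quantity with a warning, and the
#' effective n is reported.
#'
#' @param fits a list of `markov_fit`s (one per animal), or a `cohort`
#'   (whose sequences are fitted first).
#' @param conditions character vector of condition labels, one per animal;
#'   taken from the cohort when `fits` is a `cohort`, otherwise a single
#'   label may be given and is recycled.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap; fixed seed gives identical
#'   intervals across runs.
#' @return An object of class `cohort_summary`: list with `per_animal`
#'   (animal x phase quantities), `folds` (per condition and quantity:
#'   day/night fold, geometric-mean estimate with CI and n), and `ratios`
#'   (per condition and phase: rest/activity bout-length ratio with CI).
#' @export
summarize_cohort <- function(fits, conditions = "cohort", n_boot = 2000,
                             conf = 0.95, seed = NULL) {
  if (inherits(fits, "cohort")) {
    conditions <- fits$truth$condition
    fits <- lapply(fits$sequences, fit_markov)
  }
  if (length(fits) < 2L)
    stop("a cohort summary needs at least two animals", call. = FALSE)
  if (length(conditions) == 1L) conditions <- rep(conditions, length(fits))
  if (length(conditions) != length(fits))
    stop("conditions must have one entry per animal", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  per_animal <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    id <- if (!is.na(f$animal_id)) f$animal_id else paste0("animal_", i)
    # bouts started per phase from the transition counts: each R->A or A->R
    # switch opens a new bout in the phase of the origin bin
    data.frame(animal_id = id, condition = conditions[i],
               phase = rownames(f$counts),
               average_activity = unname(f$average_activity),
               mean_rest_bout_min = unname(f$mean_rest_bout_min),
               mean_activity_bout_min = unname(f$mean_activity_bout_min),
               total_bouts = unname(f$counts[, "RA"] + f$counts[, "AR"]))
  }))
  rownames(per_animal) <- NULL

  quantities <- c("average_activity", "mean_rest_bout_min",
                  "mean_activity_bout_min", "total_bouts")
  folds <- list(); ratios <- list()
  for (cond in unique(conditions)) {
    sub <- per_animal[per_animal$condition == cond, ]
    day <- sub[sub$phase == "DAY", ]
    night <- sub[sub$phase == "NIGHT", ]
    for (q in quantities) {
      fold <- day[[q]] / night[[q]]  # paired within animal
      folds[[length(folds) + 1L]] <- cbind(
        data.frame(condition = cond, quantity = q),
        gm_boot_ci(fold, n_boot, conf))
    }
    for (ph in c("DAY", "NIGHT")) {
      p <- sub[sub$phase == ph, ]
      ratio <- p$mean_rest_bout_min / p$mean_activity_bout_min
      ratios[[length(ratios) + 1L]] <- cbind(
        data.frame(condition = cond, phase = ph),
        gm_boot_ci(ratio, n_boot, conf))
    }
  }
  structure(list(per_animal = per_animal,
                 folds = do.call(rbind, folds),
                 ratios = do.call(rbind, ratios),
                 conf = conf, n_boot = n_boot),
            class = "cohort_summary")
}

# geometric mean with animal-level bootstrap CI on the log scale
gm_boot_ci <- function(x, n_boot, conf) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    warning(sum(bad), " animal(s) with undefined values excluded")
    x <- x[!bad]
  }
  n <- length(x)
  if (n == 0L)
    return(data.frame(estimate = NA_real_, lower = NA_real_,
                      upper = NA_real_, n = 0L))
  lx <- log(x)
  est <- exp(mean(lx))
  if (n == 1L)
    return(data.frame(estimate = est, lower = est, upper = est, n = 1L))
  bm <- vapply(seq_len(n_boot),
               function(b) mean(lx[sample.int(n, n, replace = TRUE)]),
               numeric(1))
  qs <- stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  data.frame(estimate = est, lower = exp(qs[1L]), upper = exp(qs[2L]), n = n)
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort summary (%d animals; geometric means with %g%% bootstrap CIs)\n",
              length(unique(x$per_animal$animal_id)), 100 * x$conf))
  cat("\nDay/night fold changes:\n")
  f <- x$folds; f[, c("estimate", "lower", "upper")] <-
    round(f[, c("estimate", "lower", "upper")], digits)
  print(f, row.names = FALSE)
  cat("\nRest/activity bout-length ratios:\n")
  r <- x$ratios; r[, c("estimate", "lower", "upper")] <-
    round(r[, c("estimate", "lower", "upper")], digits)
  print(r, row.names = FALSE)
  invisible(x)
}

#' Day/night activity fold-change report
#'
#' Extracts the day/night fold change in average activity for each
#' condition of a cohort summary and flags pairs of conditions whose
#' confidence intervals are disjoint (evidence of differing day/night
#' regulation between conditions).
#'
#' @param summary a `cohort_summary`.
#' @return A data frame with one row per condition (`condition`,
#'   `fold_day_night`, `lower`, `upper`, `n`) and an attribute
#'   `disjoint_pairs` listing condition pairs with non-overlapping CIs.
#' @export
night_day_activity_report <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  f <- summary$folds[summary$folds$quantity == "average_activity", ]
  out <- data.frame(condition = f$condition, fold_day_night = f$estimate,
                    lower = f$lower, upper = f$upper, n = f$n)
  pairs <- character(0)
  if (nrow(out) > 1L) {
    cmb <- utils::combn(nrow(out), 2L)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1L, k]; j <- cmb[2L, k]
      if (out$lower[i] > out$upper[j] || out$lower[j] > out$upper[i])
        pairs <- c(pairs, paste(out$condition[i], out$condition[j], sep = " vs "))
    }
  }
  attr(out, "disjoint_pairs") <- pairs
  out
}

#' Contrast a quantity's fold change between two condition groups
#'
#' Ratio of the day/night fold change of a quantity between two groups of
#' animals (e.g. constant darkness versus pooled light-dark), with a
#' bootstrap CI obtained by resampling animals independently within each
#' group on the log scale.
#'
#' @param summary a `cohort_summary`.
#' @param quantity one of the summary's quantities (e.g.
#'   `"mean_rest_bout_min"`).
#' @param numerator,denominator condition labels (or vectors of labels to
#'   pool, e.g. `c("LD22", "LD24", "LD26")`).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return One-row data frame: `estimate`, `lower`, `upper`.
#' @export
condition_contrast <- function(summary, quantity, numerator, denominator,
                               n_boot = 2000, conf = 0.95) {
  stopifnot(inherits(summary, "cohort_summary"))
  pa <- summary$per_animal
  fold_of <- function(conds) {
    sub <- pa[pa$condition %in% conds, ]
    day <- sub[sub$phase == "DAY", ]
    night <- sub[sub$phase == "NIGHT", ]
    lf <- log(day[[quantity]] / night[[quantity]])
    lf[is.finite(lf)]
  }
  a <- fold_of(numerator); b <- fold_of(denominator)
  if (!length(a) || !length(b))
    stop("no animals in one of the groups", call. = FALSE)
  bm <- vapply(seq_len(n_boot), function(k)
    mean(a[sample.int(length(a), replace = TRUE)]) -
      mean(b[sample.int(length(b), replace = TRUE)]), numeric(1))
  qs <- stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  data.frame(estimate = exp(mean(a) - mean(b)),
             lower = exp(qs[1L]), upper = exp(qs[2L]))
}
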