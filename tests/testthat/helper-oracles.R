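# Independent brute-force oracle for the transition-count estimator:
# walks every adjacent pair explicitly with if/else accumulation, no
# vectorisation shared with the implementation.
brute_force_transitions <- function(states, phase, gaps = integer(0)) {
  m <- matrix(0L, nrow = 2L, ncol = 4L,
              dimnames = list(c("DAY", "NIGHT"), c("RR", "RA", "AR", "AA")))
  for (i in seq_len(length(states) - 1L)) {
    if (i %in% gaps) next
    cell <- if (states[i] == "R") {
      if (states[i + 1L] == "R") "RR" else "RA"
    } else {
      if (states[i + 1L] == "R") "AR" else "AA"
    }
    row <- if (phase[i] == "DAY") 1L else 2L
    m[row, cell] <- m[row, cell] + 1L
  }
  m
}

# random A/R sequence of length n (single phase unless labels given)
random_seq <- function(n, p_active = 0.5, phase = NULL) {
  if (is.null(phase)) phase <- rep("DAY", n)
  encoded_sequence(ifelse(runif(n) < p_active, "A", "R"), phase)
}

# total variation distance between an observed bout-length distribution
# table and the model column, charging the predicted tail mass in full
tv_distance <- function(tab) {
  0.5 * (sum(abs(tab$observed - tab$predicted)) + attr(tab, "tail_mass"))
}

# published cohort-mean bout lengths (minutes), as in reference_bout_minutes()
ref_means <- list(
  ld_night = list(act = 0.75, rest = 1.75),
  ld_day   = list(act = 0.54, rest = 4.50),
  dd_night = list(act = 0.67, rest = 2.68),
  dd_day   = list(act = 0.55, rest = 4.05))
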