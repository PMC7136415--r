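#' Extract rest and activity bouts
#'
#' A bout is a maximal run of consecutive bins in the same behavioral
#' state. Bouts are extracted separately within each gap-free segment of
#' the recording, so a missing stretch never fuses two runs; within a
#' segment, rest and activity bouts strictly alternate. The first and last
#' bout of every segment are flagged `truncated` because their true length
#' is censored by the segment boundary.
#'
#' @param seq an `encoded_sequence`.
#' @return A data frame of class `bout_table` with columns `state`
#'   (`"A"`/`"R"`), `start_bin` (1-based), `length_bins`, `phase` (the
#'   phase label of the starting bin) and `truncated` (logical).
#' @export
#' @examples
#' s <- encoded_sequence(c("R", "R", "A", "A", "A", "R"), rep("DAY", 6))
#' extract_bouts(s)
extract_bouts <- function(seq) {
  stopifnot(inherits(seq, "encoded_sequence"))
  seg_start <- c(1L, seq$gaps + 1L)
  seg_end <- c(seq$gaps, seq$n_bins)
  out <- vector("list", length(seg_start))
  for (j in seq_along(seg_start)) {
    idx <- seg_start[j]:seg_end[j]
    r <- rle(seq$states[idx])
    starts <- idx[1L] + cumsum(c(0L, r$lengths[-length(r$lengths)]))
    trunc <- seq_along(r$lengths) %in% c(1L, length(r$lengths))
    out[[j]] <- data.frame(state = r$values,
                           start_bin = starts,
                           length_bins = r$lengths,
                           phase = seq$phase[starts],
                           truncated = trunc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bout_table", "data.frame")
  res
}

#' Count bouts starting in a circadian phase
#'
#' Because rest and activity bouts alternate, the numbers of rest and
#' activity bouts within any contiguous interval are equal or differ by at
#' most one, so the total count is the natural summary. The alternation
#' identity is asserted per gap-free stretch of the bout table.
#'
#' @param bouts a `bout_table` from [extract_bouts()].
#' @param phase `"DAY"`, `"NIGHT"`, or `NULL` for all bouts.
#' @return Integer count of bouts whose starting bin lies in `phase`.
#' @export
count_bouts <- function(bouts, phase = NULL) {
  stopifnot(inherits(bouts, "bout_table") || is.data.frame(bouts))
  if (nrow(bouts) == 0L) return(0L)
  # bouts alternate within each contiguous stretch: runs of the same state
  # have length one, so rest and activity totals differ by at most one
  seg <- cumsum(c(TRUE, bouts$start_bin[-1L] !=
                          bouts$start_bin[-nrow(bouts)] +
                          bouts$length_bins[-nrow(bouts)]))
  for (g in split(seq_len(nrow(bouts)), seg)) {
    st <- bouts$state[g]
    if (any(st[-1L] == st[-length(st)]))
      stop("bout table violates alternation within a contiguous segment",
           call. = FALSE)
    stopifnot(abs(sum(st == "A") - sum(st == "R")) <= 1L)
  }
  if (is.null(phase)) return(nrow(bouts))
  sum(bouts$phase %in% phase)
}
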