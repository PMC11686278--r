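# Lickometer analysis: bout detection by inter-lick-interval clustering,
# epoch summaries, peri-event alignment of the photometry trace, and
# leak-adjusted bodyweight-normalized intake.

#' Detect drinking bouts from lick timestamps
#'
#' Licks are greedily clustered: consecutive licks whose inter-lick
#' interval is at most \code{max_ili} belong to the same cluster. Clusters
#' with at least \code{min_licks} licks and spanning at least
#' \code{min_duration} seconds are bouts (at least 2 TTL pulses within one
#' second, minimum bout length 0.5 s).
#'
#' @param licks sorted, non-negative lick timestamps (seconds).
#' @param max_ili maximum inter-lick interval within a bout, seconds
#'   (inclusive; an interval of exactly \code{max_ili} joins).
#' @param min_licks minimum licks per bout.
#' @param min_duration minimum bout span (offset - onset), seconds.
#' @return data.frame with columns \code{onset}, \code{offset},
#'   \code{n_licks}, \code{duration}; zero rows if no bout qualifies.
#' @examples
#' detect_bouts(c(0, 0.4, 0.9, 3.0))  # one 3-lick bout; isolated lick dropped
#' @export
detect_bouts <- function(licks, max_ili = 1.0, min_licks = 2,
                         min_duration = 0.5) {
  if (length(licks) == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      n_licks = integer(0), duration = numeric(0)))
  if (is.unsorted(licks, strictly = TRUE) || any(licks < 0))
    stop_data("licks must be strictly increasing and non-negative")
  breaks <- which(diff(licks) > max_ili)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(licks))
  onset <- licks[starts]
  offset <- licks[ends]
  n <- ends - starts + 1L
  dur <- offset - onset
  keep <- n >= min_licks & dur >= min_duration
  data.frame(onset = onset[keep], offset = offset[keep],
             n_licks = n[keep], duration = dur[keep])
}

#' Summarize bouts within an epoch
#'
#' A bout belongs to an epoch if its onset falls in the epoch interval
#' (half-open). The motivated count keeps only bouts strictly longer than
#' \code{motivated_min_duration} (motivated drinking bouts exceed 1 s).
#'
#' @param bouts output of \code{\link{detect_bouts}}.
#' @param epoch length-2 numeric \code{c(start, end)} or a one-row epoch
#'   schedule; \code{NULL} summarizes all bouts.
#' @param motivated_min_duration strict lower duration bound for the
#'   motivated-bout count, seconds.
#' @return One-row data.frame: \code{n_bouts}, \code{n_motivated},
#'   \code{time_in_bout}, \code{mean_bout_duration} (NA when no bouts).
#' @export
summarize_bouts <- function(bouts, epoch = NULL,
                            motivated_min_duration = 1.0) {
  if (!is.null(epoch)) {
    if (is.data.frame(epoch)) epoch <- c(epoch$start_s[1], epoch$end_s[1])
    bouts <- bouts[in_interval(bouts$onset, epoch[1], epoch[2]), ,
                   drop = FALSE]
  }
  data.frame(n_bouts = nrow(bouts),
             n_motivated = sum(bouts$duration > motivated_min_duration),
             time_in_bout = sum(bouts$duration),
             mean_bout_duration = if (nrow(bouts)) mean(bouts$duration)
                                  else NA_real_)
}

#' Align the processed trace to event onsets
#'
#' Extracts, for each onset, the trace segment over \code{window} seconds
#' relative to the onset (half-open, sampled at \code{fs_eff}). Onsets whose
#' window extends beyond the trace are dropped and counted.
#'
#' @param trace a \code{processed_trace}.
#' @param onsets event onset times, seconds.
#' @param window length-2 numeric window relative to onset (default
#'   \code{c(0, 10)}: the 10 seconds following bout onset).
#' @return List: \code{t_rel} (relative time of each column), \code{rows}
#'   (matrix, one segment per usable onset), \code{mean_trace},
#'   \code{n_events}, \code{n_dropped}.
#' @export
peri_event <- function(trace, onsets, window = c(0, 10)) {
  nsamp <- floor((window[2] - window[1]) * trace$fs_eff)
  if (nsamp < 1) stop_param("window too short for the effective rate")
  t0 <- trace$time_s[1]
  n <- length(trace$z)
  rows <- list()
  dropped <- 0L
  for (on in onsets) {
    i0 <- floor((on + window[1] - t0) * trace$fs_eff) + 1
    i1 <- i0 + nsamp - 1
    if (i0 < 1 || i1 > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- trace$z[i0:i1]
  }
  if (length(rows) == 0)
    stop_data("no onset has a full window inside the trace")
  m <- do.call(rbind, rows)
  list(t_rel = window[1] + (seq_len(nsamp) - 1) / trace$fs_eff,
       rows = m, mean_trace = colMeans(m),
       n_events = nrow(m), n_dropped = dropped)
}

#' Leak-adjusted, bodyweight-normalized fluid intake
#'
#' Bottle weight loss is corrected by the loss from dummy bottles on the
#' same rack (clamped at zero), converted to volume at 1 g/ml, converted to
#' grams of solute (ethanol: 20% v/v at 0.789 g/ml; sucrose: 1% w/v), and
#' normalized to bodyweight.
#'
#' @param bottle_loss_g,dummy_leak_g bottle and dummy-bottle weight loss,
#'   grams.
#' @param bodyweight_kg bodyweight, kilograms (> 0).
#' @param solution \code{"EtOH"} (20% v/v) or \code{"sucrose"} (1% w/v).
#' @return Dose in g solute per kg bodyweight.
#' @examples
#' normalize_intake(1.2, 0.2, 0.025, "EtOH")  # 6.312 g/kg
#' @export
normalize_intake <- function(bottle_loss_g, dummy_leak_g, bodyweight_kg,
                             solution = c("EtOH", "sucrose")) {
  solution <- match.arg(solution)
  if (bottle_loss_g < 0 || dummy_leak_g < 0)
    stop_data("weights must be non-negative")
  check_scalar(bodyweight_kg, "bodyweight_kg", 0, strict = TRUE)
  net_ml <- max(bottle_loss_g - dummy_leak_g, 0)  # 1 g/ml fluid density
  grams <- switch(solution,
                  EtOH = net_ml * 0.20 * 0.789,
                  sucrose = net_ml * 0.01)
  grams / bodyweight_kg
}
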