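# Calcium-transient analysis on the z-scored trace: DID epoch extraction,
# MAD-thresholded peak detection, and reference-normalized amplitude
# distributions with AUC / peak summaries.

#' Extract the four DID analysis epochs
#'
#' From labelled access periods (W1, EtOH, W2) builds the analysis epochs:
#' the last 30 min of W1, the first and last 30 min of EtOH, and the first
#' 30 min of W2.
#'
#' @param schedule epoch schedule with labels \code{W1}, \code{EtOH},
#'   \code{W2} (see \code{\link{epoch_schedule}}).
#' @param epoch_min analysis epoch length, minutes (default 30).
#' @return Epoch schedule with labels \code{W1}, \code{EtOH1}, \code{EtOH2},
#'   \code{W2}.
#' @examples
#' segment_epochs(epoch_schedule(c("W1", "EtOH", "W2"),
#'                               c(0, 3600, 10800), c(3600, 10800, 12600)))
#' @export
segment_epochs <- function(schedule, epoch_min = 30) {
  len <- epoch_min * 60
  get <- function(lab) {
    row <- schedule[schedule$label == lab, , drop = FALSE]
    if (nrow(row) != 1) stop_data("schedule must have one ", lab, " period")
    row
  }
  w1 <- get("W1"); et <- get("EtOH"); w2 <- get("W2")
  if (w1$end_s - w1$start_s < len) stop_data("W1 access shorter than ", epoch_min, " min")
  if (et$end_s - et$start_s < 2 * len) stop_data("EtOH access shorter than ", 2 * epoch_min, " min")
  if (w2$end_s - w2$start_s < len) stop_data("W2 access shorter than ", epoch_min, " min")
  epoch_schedule(c("W1", "EtOH1", "EtOH2", "W2"),
                 c(w1$end_s - len, et$start_s, et$end_s - len, w2$start_s),
                 c(w1$end_s, et$start_s + len, et$end_s, w2$start_s + len))
}

#' Detect calcium transients on a z-scored trace
#'
#' Local maxima exceeding \code{median(z) + k_mad * 1.4826 * MAD(z)} are
#' candidate peaks; the MAD-based noise scale is robust to the transients
#' themselves inflating the sd. A candidate must also have topographic
#' prominence of at least \code{k_mad} noise units -- its height above the
#' higher of the two minima separating it from taller terrain -- which
#' rejects noise bumps riding the decay shoulder of a larger transient.
#' Peaks closer than \code{min_separation_s} keep only the larger. Event
#' amplitude is the peak value minus a local baseline, the
#' \code{baseline_percentile} of the preceding \code{baseline_window_s}.
#' Detection is invariant to adding a constant to the trace.
#'
#' @param trace a \code{processed_trace}, or a list with \code{z},
#'   \code{time_s}, \code{fs_eff}.
#' @param k_mad threshold in robust-sd units above the trace median.
#' @param min_separation_s minimum peak separation, seconds.
#' @param baseline_percentile percentile (0-100) of the preceding window
#'   used as local baseline.
#' @param baseline_window_s local-baseline window length, seconds.
#' @return data.frame with \code{time} (s) and \code{amplitude} (z-units),
#'   sorted by time.
#' @export
detect_transients <- function(trace, k_mad = 2.5, min_separation_s = 1.0,
                              baseline_percentile = 10,
                              baseline_window_s = 5) {
  z <- trace$z
  if (length(z) == 0) stop_data("empty trace")
  fs <- trace$fs_eff
  noise <- stats::mad(z)  # 1.4826 * MAD
  thr <- stats::median(z) + k_mad * noise
  n <- length(z)
  if (n < 3) return(data.frame(time = numeric(0), amplitude = numeric(0)))
  i <- 2:(n - 1)
  cand <- i[z[i] > z[i - 1] & z[i] >= z[i + 1] & z[i] > thr]
  if (length(cand) == 0)
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  cand <- cand[peak_prominence(z, cand) >= k_mad * noise]
  if (length(cand) == 0)
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  # enforce separation: greedy from the tallest peak down
  ord <- cand[order(z[cand], decreasing = TRUE)]
  min_gap <- min_separation_s * fs
  kept <- integer(0)
  for (p in ord)
    if (all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  kept <- sort(kept)
  win <- max(1, round(baseline_window_s * fs))
  base <- vapply(kept, function(p) {
    seg <- z[max(1, p - win):max(1, p - 1)]
    stats::quantile(seg, baseline_percentile / 100, names = FALSE)
  }, numeric(1))
  data.frame(time = trace$time_s[kept], amplitude = z[kept] - base)
}

#' Reference-normalized amplitude distribution
#'
#' Bins the amplitudes of one epoch's events and divides each bin count by
#' the total event count of the reference epoch (the W1 epoch of the same
#' day), so the reference epoch's own normalized distribution sums to 1 and
#' an epoch with added events has normalized total above 1. The alternative
#' per-bin-ratio reading (each bin divided by the reference's count in that
#' bin) is available via \code{per_bin_ratio = TRUE}.
#'
#' @param events events data.frame (\code{time}, \code{amplitude}) for the
#'   epoch of interest; only events with onset in \code{epoch} are used.
#' @param epoch length-2 numeric or one-row schedule for the epoch.
#' @param reference_events,reference_epoch the reference (W1) events and
#'   epoch.
#' @param bin_width amplitude bin width, z-units (default 0.5).
#' @param amp_range amplitude range covered by the bins (default
#'   \code{c(0, 10)} z; half-open bins).
#' @param per_bin_ratio use the per-bin ratio normalization instead.
#' @return data.frame: \code{bin_left}, \code{bin_right}, \code{bin_center},
#'   \code{count}, \code{rate_per_min}, \code{normalized}; attribute
#'   \code{reference_total}.
#' @export
amplitude_distribution <- function(events, epoch, reference_events,
                                   reference_epoch, bin_width = 0.5,
                                   amp_range = c(0, 10),
                                   per_bin_ratio = FALSE) {
  as_iv <- function(e) if (is.data.frame(e)) c(e$start_s[1], e$end_s[1]) else e
  epoch <- as_iv(epoch); reference_epoch <- as_iv(reference_epoch)
  if (diff(epoch) <= 0 || diff(reference_epoch) <= 0)
    stop_param("epochs must have positive duration")
  edges <- seq(amp_range[1], amp_range[2], by = bin_width)
  bin_counts <- function(ev, iv) {
    a <- ev$amplitude[in_interval(ev$time, iv[1], iv[2])]
    a <- a[a >= amp_range[1] & a < amp_range[2]]
    tabulate(findInterval(a, edges), nbins = length(edges) - 1)
  }
  cnt <- bin_counts(events, epoch)
  ref <- bin_counts(reference_events, reference_epoch)
  ref_total <- sum(ref)
  if (ref_total == 0) stop_data("reference epoch has no events")
  normalized <- if (per_bin_ratio) ifelse(ref > 0, cnt / ref, NA_real_)
                else cnt / ref_total
  out <- data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
                    bin_center = (edges[-length(edges)] + edges[-1]) / 2,
                    count = cnt,
                    rate_per_min = cnt / (diff(epoch) / 60),
                    normalized = normalized)
  attr(out, "reference_total") <- ref_total
  out
}

# topographic prominence: height above the higher of the two minima
# separating the peak from the nearest strictly taller sample on each side
# (series end counts as a base when no taller terrain exists)
peak_prominence <- function(z, peaks) {
  n <- length(z)
  vapply(peaks, function(p) {
    h <- z[p]
    left <- if (p == 1) h else {
      seg <- z[(p - 1):1]
      stopi <- which(seg > h)[1]
      min(seg[seq_len(if (is.na(stopi)) length(seg) else stopi)])
    }
    right <- if (p == n) h else {
      seg <- z[(p + 1):n]
      stopi <- which(seg > h)[1]
      min(seg[seq_len(if (is.na(stopi)) length(seg) else stopi)])
    }
    h - max(left, right)
  }, numeric(1))
}

#' AUC and peak of an amplitude distribution
#'
#' AUC is the trapezoidal integral of the normalized values over the bin
#' centers; the peak is the center of the maximum bin, ties broken toward
#' the lower amplitude.
#'
#' @param dist output of \code{\link{amplitude_distribution}}.
#' @return List: \code{auc}, \code{peak_amplitude}.
#' @export
summarize_distribution <- function(dist) {
  y <- dist$normalized
  if (all(y == 0)) stop_data("all-zero distribution")
  x <- dist$bin_center
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  list(auc = auc, peak_amplitude = x[which.max(y)])
}
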