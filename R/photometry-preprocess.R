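# Photometry preprocessing: median/lowpass denoising at the acquisition
# rate, trace-start exclusion, block-mean downsampling, isosbestic
# motion correction by linear fit, whole-trace z-scoring.

#' Denoise a fluorescence channel
#'
#' Median filter (to remove single-sample electrical artifacts) followed by
#' a zero-phase second-order Butterworth lowpass (forward-backward, so no
#' phase distortion of transient onsets).
#'
#' @param x numeric channel at sampling rate \code{fs}.
#' @param fs sampling rate, Hz.
#' @param median_window odd window length in samples (default 5).
#' @param lowpass_cutoff lowpass cutoff, Hz (default 3; must be below
#'   Nyquist).
#' @return Denoised channel, same length.
#' @export
denoise <- function(x, fs, median_window = 5, lowpass_cutoff = 3) {
  if (median_window %% 2 == 0 || median_window < 3)
    stop_param("median_window must be odd and >= 3")
  if (lowpass_cutoff <= 0 || lowpass_cutoff >= fs / 2)
    stop_param("lowpass_cutoff must be in (0, fs/2)")
  y <- stats::runmed(x, median_window, endrule = "median")
  bf <- signal::butter(2, lowpass_cutoff / (fs / 2))
  zero_phase(bf, y, fs, lowpass_cutoff)
}

# forward-backward filtering with odd-reflection padding so the filter's
# zero initial conditions cannot leak edge transients into the trace
zero_phase <- function(bf, x, fs, cutoff) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  npad <- min(n - 1, ceiling(30 * fs / cutoff))
  padded <- c(2 * xc[1] - xc[(npad + 1):2],
              xc,
              2 * xc[n] - xc[(n - 1):(n - npad)])
  out <- signal::filtfilt(bf, padded)
  out[(npad + 1):(npad + n)] + mu
}

#' Exclude the start of a session
#'
#' Drops the initial segment contaminated by transfer to the apparatus or
#' bottle changes: 150 s for elevated plus maze (EPM), 400 s for open field
#' (OF), 1000 s for the drinking session (DID). The epoch schedule is
#' clipped to the retained support.
#'
#' @param session a \code{photometry_session}.
#' @param assay one of \code{"DID"}, \code{"EPM"}, \code{"OF"}.
#' @param exclusion_override optional exclusion in seconds replacing the
#'   assay default.
#' @return The trimmed session.
#' @export
trim_start <- function(session, assay = session$assay,
                       exclusion_override = NULL) {
  exclusions <- c(EPM = 150, OF = 400, DID = 1000)
  if (is.null(exclusion_override)) {
    if (!assay %in% names(exclusions)) stop_param("unknown assay: ", assay)
    excl <- exclusions[[assay]]
  } else excl <- check_scalar(exclusion_override, "exclusion_override", 0)
  dur <- length(session$time_s) / session$fs
  if (dur <= excl)
    stop_data(sprintf("session (%.0f s) is not longer than the %s exclusion (%.0f s)",
                      dur, assay, excl))
  keep <- session$time_s >= excl
  session$time_s <- session$time_s[keep]
  session$f465 <- session$f465[keep]
  session$f405 <- session$f405[keep]
  session$licks <- session$licks[session$licks >= excl]
  es <- session$epoch_schedule
  if (!is.null(es)) {
    es$start_s <- pmax(es$start_s, excl)
    session$epoch_schedule <- es[es$end_s > es$start_s, , drop = FALSE]
  }
  session
}

#' Downsample a channel by block means
#'
#' Output sample k is the mean of input block k of length \code{factor};
#' a trailing partial block is dropped. Block averaging (rather than
#' decimation) suppresses residual high-frequency noise.
#'
#' @param x numeric channel.
#' @param factor integer >= 1.
#' @return Downsampled channel of length \code{floor(length(x)/factor)}.
#' @examples
#' downsample_mean(1:100, 100)  # 50.5
#' @export
downsample_mean <- function(x, factor = 100) {
  if (factor < 1 || factor != round(factor))
    stop_param("factor must be an integer >= 1")
  if (factor == 1) return(x)
  nblock <- floor(length(x) / factor)
  if (nblock == 0) return(numeric(0))
  colMeans(matrix(x[seq_len(nblock * factor)], nrow = factor))
}

#' Isosbestic motion correction
#'
#' Fits the best linear (ordinary least squares) transform of the 405 nm
#' isosbestic channel to the 465 nm GCaMP channel and subtracts the fitted
#' component. The isosbestic channel carries motion and bleaching but no
#' calcium signal, so the residual retains calcium transients while the
#' shared artifacts cancel.
#'
#' @param f465,f405 equal-length numeric channels.
#' @return List with \code{corrected} (zero-mean residual) and \code{fit}
#'   (slope, intercept, Pearson r of the two channels).
#' @export
motion_correct <- function(f465, f405) {
  if (length(f465) != length(f405)) stop_param("channels must have equal length")
  if (length(f465) < 3) stop_param("need >= 3 samples")
  if (stats::sd(f405) == 0)
    stop_data("isosbestic channel is constant; motion fit is degenerate")
  cf <- stats::coef(stats::lm.fit(cbind(1, f405), f465))
  fitted <- cf[1] + cf[2] * f405
  list(corrected = f465 - fitted,
       fit = list(slope = unname(cf[2]), intercept = unname(cf[1]),
                  r = stats::cor(f465, f405)))
}

#' Whole-trace z-scoring
#'
#' Subtracts the mean of the whole analyzed trace and divides by its
#' standard deviation (sample sd, denominator n - 1).
#'
#' @param x numeric trace, length >= 2, nonzero variance.
#' @return z-scored trace (mean 0, sd 1).
#' @export
zscore_trace <- function(x) {
  if (length(x) < 2) stop_param("need >= 2 samples")
  s <- stats::sd(x)
  if (s == 0) stop_data("trace has zero variance; z-score undefined")
  (x - mean(x)) / s
}

#' Full preprocessing pipeline
#'
#' Runs, in order: denoise both channels at the acquisition rate, exclude
#' the trace start per assay, block-mean downsample both channels, fit and
#' subtract the isosbestic motion component, and z-score the whole trace.
#' Every step and parameter is recorded in the returned provenance.
#'
#' @param session a \code{photometry_session}.
#' @param median_window,lowpass_cutoff see \code{\link{denoise}}.
#' @param factor downsampling factor (default 100).
#' @param exclusion_override optional trim override, seconds.
#' @return A \code{processed_trace}: \code{time_s}, \code{z}, \code{fs_eff},
#'   \code{motion_fit}, \code{licks}, \code{epoch_schedule},
#'   \code{provenance}.
#' @export
preprocess <- function(session, median_window = 5, lowpass_cutoff = 3,
                       factor = 100, exclusion_override = NULL) {
  s <- session
  s$f465 <- denoise(s$f465, s$fs, median_window, lowpass_cutoff)
  s$f405 <- denoise(s$f405, s$fs, median_window, lowpass_cutoff)
  s <- trim_start(s, exclusion_override = exclusion_override)
  t_ds <- downsample_mean(s$time_s, factor)
  f465 <- downsample_mean(s$f465, factor)
  f405 <- downsample_mean(s$f405, factor)
  mc <- motion_correct(f465, f405)
  z <- zscore_trace(mc$corrected)
  structure(list(
    time_s = t_ds, z = z, fs_eff = s$fs / factor,
    motion_fit = mc$fit, licks = s$licks,
    epoch_schedule = s$epoch_schedule,
    provenance = list(
      denoise = list(median_window = median_window,
                     lowpass_cutoff = lowpass_cutoff),
      trim = list(assay = session$assay,
                  exclusion_override = exclusion_override),
      downsample = list(factor = factor),
      motion_correct = mc$fit,
      zscore = list(ddof = 1))),
    class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("processed trace: %d samples at %.4f Hz, [%.1f, %.1f) s\n",
              length(x$z), x$fs_eff, x$time_s[1],
              x$time_s[length(x$time_s)] + 1 / x$fs_eff))
  cat(sprintf("  motion fit: slope %.3f, intercept %.3f, r %.3f\n",
              x$motion_fit$slope, x$motion_fit$intercept, x$motion_fit$r))
  invisible(x)
}

#' @export
plot.processed_trace <- function(x, ...) {
  plot(x$time_s, x$z, type = "l", xlab = "time (s)", ylab = "z",
       main = "motion-corrected z-scored GCaMP trace", ...)
  invisible(x)
}
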