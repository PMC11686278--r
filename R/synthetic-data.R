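# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. All randomness flows through one seeded RNG per call (local
# to the call via a private environment switch; no global state is left
# modified).

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' Parameters for the photometry simulator
#'
#' Defaults describe a drinking-session recording: GCaMP6s-like transients
#' (instantaneous rise, exponential decay), a slow shared motion artifact,
#' single-exponential photobleaching toward an asymptote, and white sensor
#' noise.
#'
#' @param duration_s session length in seconds.
#' @param fs sampling rate, Hz.
#' @param transient_rate calcium-transient rate, events/min. Either a single
#'   rate or a named vector matching the labels of \code{epoch_schedule},
#'   giving a piecewise-constant rate.
#' @param transient_amp_mean,transient_amp_sd mean and sd of transient peak
#'   amplitudes (arbitrary fluorescence units; amplitudes are lognormal with
#'   these moments). \code{transient_amp_mean} may also be a named
#'   per-epoch vector, like \code{transient_rate}.
#' @param decay_tau transient decay time constant, seconds (GCaMP6s-like).
#' @param motion_amp sd of the shared motion artifact (arbitrary units).
#' @param motion_gain_465 gain applied to the motion trace in the 465 channel
#'   (the 405 channel carries the motion trace at unit gain).
#' @param bleach_tau photobleaching time constant, seconds.
#' @param bleach_frac fraction of the initial baseline that decays away.
#' @param baseline_465,baseline_405 initial per-channel baselines.
#' @param noise_sd white sensor noise sd per channel.
#' @param epoch_schedule labelled access intervals (see
#'   \code{\link{epoch_schedule}}); defaults to a single "all" interval.
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @return A validated parameter list of class \code{photometry_sim_params}.
#' @export
photometry_sim_params <- function(duration_s = 300, fs = 1017.25,
                                  transient_rate = 6,
                                  transient_amp_mean = 5,
                                  transient_amp_sd = 1.5,
                                  decay_tau = 1.5,
                                  motion_amp = 1, motion_gain_465 = 1.5,
                                  bleach_tau = 600, bleach_frac = 0.2,
                                  baseline_465 = 100, baseline_405 = 60,
                                  noise_sd = 0.5,
                                  epoch_schedule = NULL, seed = 1L) {
  check_scalar(duration_s, "duration_s", 0, strict = TRUE)
  check_scalar(fs, "fs", 0, strict = TRUE)
  if (any(transient_rate < 0)) stop_param("transient_rate must be >= 0")
  if (any(transient_amp_mean < 0)) stop_param("transient_amp_mean must be >= 0")
  check_scalar(transient_amp_sd, "transient_amp_sd", 0)
  check_scalar(decay_tau, "decay_tau", 0)
  check_scalar(motion_amp, "motion_amp", 0)
  check_scalar(bleach_tau, "bleach_tau", 0)
  check_scalar(noise_sd, "noise_sd", 0)
  if (is.null(epoch_schedule))
    epoch_schedule <- data.frame(label = "all", start_s = 0,
                                 end_s = duration_s)
  if (any(epoch_schedule$end_s > duration_s + 1e-9))
    stop_param("epoch schedule extends past duration_s")
  for (nm in c("transient_rate", "transient_amp_mean")) {
    v <- get(nm)
    if (length(v) > 1 && !all(epoch_schedule$label %in% names(v)))
      stop_param("per-epoch ", nm, " must name every schedule label")
  }
  structure(list(duration_s = duration_s, fs = fs,
                 transient_rate = transient_rate,
                 transient_amp_mean = transient_amp_mean,
                 transient_amp_sd = transient_amp_sd,
                 decay_tau = decay_tau, motion_amp = motion_amp,
                 motion_gain_465 = motion_gain_465,
                 bleach_tau = bleach_tau, bleach_frac = bleach_frac,
                 baseline_465 = baseline_465, baseline_405 = baseline_405,
                 noise_sd = noise_sd, epoch_schedule = epoch_schedule,
                 seed = seed),
            class = "photometry_sim_params")
}

# slow artifact shared by both channels: white noise lowpassed at cutoff_hz,
# rescaled to unit sd before applying the requested amplitude
simulate_motion <- function(n, fs, cutoff_hz = 0.5) {
  w <- stats::rnorm(n)
  if (n < 24) return(w)  # too short to filter; raw noise
  bf <- signal::butter(2, min(cutoff_hz / (fs / 2), 0.99))
  m <- signal::filtfilt(bf, w)
  s <- stats::sd(m)
  if (s > 0) m / s else m
}

lognormal_pars <- function(mean, sd) {
  if (mean <= 0) stop_param("transient_amp_mean must be > 0 when events occur")
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate a two-channel photometry session
#'
#' The 465 nm channel is
#' \code{bleach(t) + sum of transients + gain * motion(t) + noise};
#' the 405 nm isosbestic channel is \code{bleach'(t) + motion(t) + noise'}.
#' Both channels share the identical motion trace, which is what isosbestic
#' motion correction exploits. Transient onset times are Poisson
#' (piecewise-constant rate over the epoch schedule), amplitudes lognormal,
#' and each transient decays exponentially with \code{decay_tau}.
#'
#' @param params a \code{\link{photometry_sim_params}} object.
#' @param licks optional lick timestamps (seconds) attached to the session.
#' @return A list with \code{session} (class \code{photometry_session}:
#'   \code{time_s}, \code{f465}, \code{f405}, \code{fs}, \code{assay},
#'   \code{licks}, \code{epoch_schedule}) and \code{truth} (transient times
#'   and amplitudes, the motion trace, and the bleach curves).
#' @examples
#' sim <- simulate_photometry(photometry_sim_params(duration_s = 20, seed = 7))
#' length(sim$truth$transient_times)
#' @export
simulate_photometry <- function(params, licks = numeric(0)) {
  if (!inherits(params, "photometry_sim_params"))
    params <- do.call(photometry_sim_params, params)
  p <- params
  n <- floor(p$duration_s * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  with_seed(p$seed, {
    # piecewise-constant Poisson transient times, per-epoch amplitude mean
    times <- numeric(0); amps <- numeric(0)
    for (i in seq_len(nrow(p$epoch_schedule))) {
      lab <- p$epoch_schedule$label[i]
      rate <- if (length(p$transient_rate) > 1) p$transient_rate[[lab]]
              else p$transient_rate
      amp_mean <- if (length(p$transient_amp_mean) > 1)
        p$transient_amp_mean[[lab]] else p$transient_amp_mean
      dur <- p$epoch_schedule$end_s[i] - p$epoch_schedule$start_s[i]
      k <- stats::rpois(1, rate / 60 * dur)
      if (k > 0) {
        times <- c(times, sort(stats::runif(k, p$epoch_schedule$start_s[i],
                                            p$epoch_schedule$end_s[i])))
        lp <- lognormal_pars(amp_mean, p$transient_amp_sd)
        amps <- c(amps, stats::rlnorm(k, lp$meanlog, lp$sdlog))
      }
    }
    ord <- order(times)
    times <- times[ord]; amps <- amps[ord]

    transients <- numeric(n)
    if (length(times) > 0 && p$decay_tau > 0) {
      for (j in seq_along(times)) {
        i0 <- floor(times[j] * p$fs) + 1
        i1 <- min(n, i0 + ceiling(6 * p$decay_tau * p$fs))
        if (i0 <= n) {
          idx <- i0:i1
          transients[idx] <- transients[idx] +
            amps[j] * exp(-(t[idx] - times[j]) / p$decay_tau)
        }
      }
    }

    motion <- if (p$motion_amp > 0) p$motion_amp * simulate_motion(n, p$fs)
              else numeric(n)
    bleach465 <- p$baseline_465 *
      ((1 - p$bleach_frac) + p$bleach_frac * exp(-t / p$bleach_tau))
    bleach405 <- p$baseline_405 *
      ((1 - p$bleach_frac) + p$bleach_frac * exp(-t / p$bleach_tau))
    f465 <- bleach465 + transients + p$motion_gain_465 * motion +
      stats::rnorm(n, 0, p$noise_sd)
    f405 <- bleach405 + motion + stats::rnorm(n, 0, p$noise_sd)

    session <- structure(list(time_s = t, f465 = f465, f405 = f405,
                              fs = p$fs, assay = "DID", licks = licks,
                              epoch_schedule = p$epoch_schedule),
                         class = "photometry_session")
    truth <- list(transient_times = times, transient_amps = amps,
                  motion_trace = motion, bleach_465 = bleach465,
                  bleach_405 = bleach405)
    list(session = session, truth = truth)
  })
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("photometry session: %.1f s at %.2f Hz (%d samples), assay %s\n",
              length(x$time_s) / x$fs, x$fs, length(x$time_s), x$assay))
  cat(sprintf("  licks: %d; epochs: %s\n", length(x$licks),
              paste(x$epoch_schedule$label, collapse = ", ")))
  invisible(x)
}

#' Simulate a lickometer TTL train from a bout schedule
#'
#' Each scheduled bout emits \code{n_licks} timestamps whose inter-lick
#' intervals are drawn uniform on
#' \code{[max(0.15, 0.5/(n_licks-1)), 0.95]} seconds, so by construction
#' every bout spans at least 0.5 s with all intervals below 1 s, and is
#' therefore recovered by \code{\link{detect_bouts}} at the default rule.
#'
#' @param bout_schedule data.frame with columns \code{onset} (seconds) and
#'   \code{n_licks} (>= 2), onsets strictly increasing.
#' @param seed integer seed.
#' @return Numeric vector of sorted lick timestamps (seconds).
#' @export
simulate_licks <- function(bout_schedule, seed = 1L) {
  if (nrow(bout_schedule) == 0) return(numeric(0))
  if (any(bout_schedule$n_licks < 2)) stop_param("n_licks must be >= 2")
  if (is.unsorted(bout_schedule$onset, strictly = TRUE))
    stop_param("bout onsets must be strictly increasing")
  with_seed(seed, {
    out <- vector("list", nrow(bout_schedule))
    prev_end <- -Inf
    for (i in seq_len(nrow(bout_schedule))) {
      k <- bout_schedule$n_licks[i]
      lo <- max(0.15, 0.5 / (k - 1))
      ili <- stats::runif(k - 1, lo, 0.95)
      licks <- bout_schedule$onset[i] + c(0, cumsum(ili))
      if (licks[1] - prev_end <= 1.0)
        stop_param("bout schedule too tight: gap between bouts must exceed 1 s")
      prev_end <- licks[k]
      out[[i]] <- licks
    }
    unlist(out)
  })
}

#' Simulate a spontaneous PSC event stream with a drug wash-on step
#'
#' Event times are homogeneous Poisson at \code{baseline_rate} during the
#' baseline and washout windows and at \code{baseline_rate * wash_multiplier}
#' during the wash window; amplitudes are i.i.d. lognormal with mean
#' \code{amp_mean}.
#'
#' @param baseline_rate events/s (Hz).
#' @param amp_mean mean event amplitude, pA.
#' @param amp_cv coefficient of variation of amplitudes.
#' @param wash_multiplier multiplicative change in event rate during wash-on.
#' @param windows named list of \code{c(start, end)} second pairs:
#'   \code{baseline}, \code{wash}, \code{washout} (ordered, disjoint).
#' @param seed integer seed.
#' @return A \code{psc_stream}: \code{event_times}, \code{amplitudes},
#'   \code{windows}, \code{polarity}.
#' @export
simulate_psc_stream <- function(baseline_rate, amp_mean = 20, amp_cv = 0.3,
                                wash_multiplier = 1,
                                windows = list(baseline = c(0, 300),
                                               wash = c(300, 900),
                                               washout = c(900, 1200)),
                                seed = 1L) {
  check_scalar(baseline_rate, "baseline_rate", 0)
  check_scalar(wash_multiplier, "wash_multiplier", 0)
  w <- windows
  if (!(w$baseline[2] <= w$wash[1] && w$wash[2] <= w$washout[1]))
    stop_param("windows must be ordered baseline < wash < washout")
  with_seed(seed, {
    draw <- function(win, rate) {
      k <- stats::rpois(1, rate * (win[2] - win[1]))
      if (k > 0) sort(stats::runif(k, win[1], win[2])) else numeric(0)
    }
    times <- c(draw(w$baseline, baseline_rate),
               draw(w$wash, baseline_rate * wash_multiplier),
               draw(w$washout, baseline_rate))
    amps <- if (length(times) > 0) {
      lp <- lognormal_pars(amp_mean, amp_cv * amp_mean)
      stats::rlnorm(length(times), lp$meanlog, lp$sdlog)
    } else numeric(0)
    psc_stream(times, amps, windows)
  })
}

#' Simulate calibration-standard peak-area ratios
#'
#' Replicate analyte/internal-standard ratios at each nominal concentration
#' follow \code{Normal(slope * C + intercept, cv * mean)} -- proportional
#' noise, the error structure 1/C weighting addresses.
#'
#' @param true_slope,true_intercept line parameters (ratio per conc unit;
#'   ratio).
#' @param levels nominal concentrations (a blank at 0 is allowed).
#' @param replicates replicates per level.
#' @param cv proportional noise coefficient.
#' @param seed integer seed.
#' @return data.frame with \code{nominal_conc}, \code{replicate_id},
#'   \code{ratio}.
#' @export
simulate_calibration <- function(true_slope, true_intercept = 0,
                                 levels = serial_dilution_design(),
                                 replicates = 3, cv = 0.05, seed = 1L) {
  check_scalar(cv, "cv", 0)
  if (any(levels < 0)) stop_param("levels must be >= 0")
  with_seed(seed, {
    grid <- expand.grid(replicate_id = seq_len(replicates),
                        nominal_conc = levels)
    mu <- true_slope * grid$nominal_conc + true_intercept
    grid$ratio <- stats::rnorm(nrow(grid), mu, cv * abs(mu))
    grid[, c("nominal_conc", "replicate_id", "ratio")]
  })
}

#' Simulate a sparse genes-by-cells count matrix
#'
#' Each targeted gene is detected (count > 0) in each cell independently
#' with its target probability; positive counts are \code{1 + Poisson}.
#' Untargeted genes receive a low background detection probability.
#'
#' @param n_genes,n_cells matrix dimensions. Gene names default to
#'   \code{gene1..n} with targeted names taken from \code{target_fractions}.
#' @param target_fractions named numeric vector, gene -> detection
#'   probability in [0, 1].
#' @param mean_count mean of the positive-count distribution.
#' @param background_p detection probability for untargeted genes.
#' @param seed integer seed.
#' @return A \code{Matrix::dgCMatrix} with gene rownames and barcode
#'   colnames.
#' @export
simulate_counts <- function(n_genes, n_cells, target_fractions = numeric(0),
                            mean_count = 2, background_p = 0.05, seed = 1L) {
  if (any(target_fractions < 0 | target_fractions > 1))
    stop_param("target fractions must be in [0, 1]")
  if (length(target_fractions) > n_genes)
    stop_param("more targeted genes than n_genes")
  genes <- paste0("gene", seq_len(n_genes))
  genes[seq_along(target_fractions)] <- names(target_fractions)
  p <- rep(background_p, n_genes)
  p[seq_along(target_fractions)] <- unname(target_fractions)
  with_seed(seed, {
    ij <- lapply(seq_len(n_genes), function(g) {
      pos <- which(stats::runif(n_cells) < p[g])
      if (length(pos) == 0) return(NULL)
      cbind(g, pos, 1 + stats::rpois(length(pos), max(mean_count - 1, 0)))
    })
    ij <- do.call(rbind, ij)
    m <- if (is.null(ij)) {
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(n_genes, n_cells))
    } else {
      Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = ij[, 3],
                           dims = c(n_genes, n_cells))
    }
    dimnames(m) <- list(genes, paste0("cell", seq_len(n_cells)))
    m
  })
}
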