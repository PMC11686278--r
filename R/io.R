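# Delimited-text I/O for sessions, lick trains, epoch schedules, processed
# traces, and PSC streams. All tables are plain tab-separated text with
# headers; lick/TTL files are one timestamp per line.

#' Write a photometry session as delimited text
#'
#' Writes three files: the two-channel table (\code{time_s, f465, f405}),
#' a TTL timestamp list (one time per line), and an epoch-schedule sidecar
#' (\code{label, start_s, end_s}).
#'
#' @param session a \code{photometry_session}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_session <- function(session, dir, prefix = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".tsv", "_licks.txt",
                                           "_epochs.tsv")))
  utils::write.table(
    data.frame(time_s = session$time_s, f465 = session$f465,
               f405 = session$f405),
    paths[1], sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(format(session$licks, scientific = FALSE, trim = TRUE), paths[2])
  utils::write.table(session$epoch_schedule, paths[3], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a photometry session written by \code{\link{write_session}}
#'
#' @param path path to the two-channel table; the \code{_licks.txt} and
#'   \code{_epochs.tsv} sidecars are found next to it.
#' @param fs sampling rate, Hz; inferred from the time column if omitted.
#' @param assay assay label (\code{"DID"}, \code{"EPM"}, \code{"OF"}).
#' @return A \code{photometry_session}.
#' @export
read_session <- function(path, fs = NULL, assay = "DID") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stem <- sub("\\.tsv$", "", path)
  lick_path <- paste0(stem, "_licks.txt")
  epoch_path <- paste0(stem, "_epochs.tsv")
  licks <- if (file.exists(lick_path) && file.size(lick_path) > 0)
    as.numeric(readLines(lick_path)) else numeric(0)
  epochs <- if (file.exists(epoch_path))
    utils::read.table(epoch_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time_s))
  structure(list(time_s = d$time_s, f465 = d$f465, f405 = d$f405,
                 fs = fs, assay = assay, licks = licks,
                 epoch_schedule = epochs),
            class = "photometry_session")
}

#' Write a processed trace with its provenance sidecar
#'
#' @param trace a \code{processed_trace}.
#' @param path output path for the \code{time_s, z} table; provenance goes
#'   to \code{<path>.provenance.txt}.
#' @return Invisibly, the table path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(data.frame(time_s = trace$time_s, z = trace$z),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  prov <- vapply(names(trace$provenance), function(step) {
    pars <- trace$provenance[[step]]
    paste0(step, ": ",
           paste(names(pars), vapply(pars, function(v)
             paste(format(v), collapse = ","), character(1)),
             sep = "=", collapse = "; "))
  }, character(1))
  writeLines(prov, paste0(path, ".provenance.txt"))
  invisible(path)
}

#' Write a PSC stream with its window sidecar
#'
#' @param stream a \code{psc_stream}.
#' @param path output path for the \code{time_s, amplitude_pA} table;
#'   windows go to \code{<path>.windows.tsv}.
#' @return Invisibly, the table path.
#' @export
write_psc <- function(stream, path) {
  utils::write.table(data.frame(time_s = stream$event_times,
                                amplitude_pA = stream$amplitudes),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  w <- stream$windows
  utils::write.table(
    data.frame(label = names(w),
               start_s = vapply(w, `[`, numeric(1), 1),
               end_s = vapply(w, `[`, numeric(1), 2)),
    paste0(path, ".windows.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' Read a PSC stream written by \code{\link{write_psc}}
#'
#' @param path path to the event table.
#' @return A \code{psc_stream}.
#' @export
read_psc <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  w <- utils::read.table(paste0(path, ".windows.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  windows <- stats::setNames(
    lapply(seq_len(nrow(w)), function(i) c(w$start_s[i], w$end_s[i])),
    w$label)
  psc_stream(d$time_s, d$amplitude_pA, windows)
}
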