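# Plain-text epoch storage: one delimited matrix file per trial plus a JSON
# sidecar carrying sampling rate, time axis, trial conditions and
# participant metadata.

#' Write epochs as delimited matrices with a JSON sidecar
#'
#' Each trial is stored as a \code{channels x samples} CSV (no header);
#' \code{epochs.json} records the sampling rate, epoch start time, trial
#' condition labels, participant metadata and the per-trial file names.
#'
#' @param epochs an \code{ms_epochs}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- dim(epochs$data)[1]
  files <- sprintf("trial_%04d.csv", seq_len(nt))
  for (tr in seq_len(nt)) {
    utils::write.table(epochs$data[tr, , ], file.path(dir, files[tr]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  sidecar <- list(
    sampling_rate = epochs$sampling_rate,
    time_start_ms = epochs$times[1],
    n_channels = dim(epochs$data)[2],
    n_samples = dim(epochs$data)[3],
    condition = as.list(epochs$condition),
    participant_id = epochs$participant_id,
    group = epochs$group,
    files = as.list(files)
  )
  jsonlite::write_json(sidecar, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read epochs written by \code{\link{write_epochs}}
#'
#' @param dir directory containing \code{epochs.json} and the per-trial
#'   matrix files.
#' @return an \code{ms_epochs}.
#' @export
read_epochs <- function(dir) {
  sc_path <- file.path(dir, "epochs.json")
  if (!file.exists(sc_path)) {
    stop("no epochs.json sidecar in ", dir, call. = FALSE)
  }
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (length(sc$files) == 0L) stop("sidecar lists no trial files",
                                   call. = FALSE)
  if (length(sc$condition) != length(sc$files)) {
    stop("sidecar condition labels do not match the trial count",
         call. = FALSE)
  }
  dat <- array(0, dim = c(length(sc$files), sc$n_channels, sc$n_samples))
  for (tr in seq_along(sc$files)) {
    m <- as.matrix(utils::read.table(file.path(dir, sc$files[tr]),
                                     sep = ",", header = FALSE))
    if (nrow(m) != sc$n_channels || ncol(m) != sc$n_samples) {
      stop(sprintf("trial file %s: inconsistent channel/sample count",
                   sc$files[tr]), call. = FALSE)
    }
    dat[tr, , ] <- m
  }
  times <- sc$time_start_ms + (seq_len(sc$n_samples) - 1L) *
    1000 / sc$sampling_rate
  new_ms_epochs(dat, sc$sampling_rate, times, sc$condition,
                sc$participant_id %||% NA_character_,
                sc$group %||% NA_character_)
}
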