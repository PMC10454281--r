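#' Epoched EEG
#'
#' Container for response-locked epochs: a trials x channels x samples
#' array with a millisecond time axis relative to the button press, channel
#' labels and per-trial metadata (subject, group, hand).
#'
#' @param data numeric array, trials x channels x samples (microvolts, or
#'   CSD units after the surface Laplacian).
#' @param times numeric vector of sample times in ms; strictly increasing,
#'   uniform step `1000/srate`, containing 0 ms.
#' @param srate sampling rate in Hz.
#' @param labels channel labels.
#' @param metadata data.frame with one row per trial (columns such as
#'   `subject`, `group`, `hand`); defaults to trial indices.
#' @param csd logical; TRUE once the surface-Laplacian transform has been
#'   applied (values then in µV/m² on the unit-radius head).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, srate, labels = NULL, metadata = NULL,
                       csd = FALSE) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop("data must be trials x channels x samples")
  if (!all(is.finite(data))) stop("epoch data contains non-finite values")
  nt <- dim(data)[3]
  if (length(times) != nt) stop("time axis length does not match data")
  step <- 1000 / srate
  if (any(diff(times) <= 0) || max(abs(diff(times) - step)) > 1e-6 * step)
    stop("time axis must be strictly increasing with uniform step 1000/srate")
  if (min(times) > 0 || max(times) < 0)
    stop("0 ms (the locking event) must lie inside the epoch")
  if (is.null(labels)) labels <- paste0("Ch", seq_len(dim(data)[2]))
  if (length(labels) != dim(data)[2])
    stop("label count does not match channel count")
  if (is.null(metadata))
    metadata <- data.frame(trial = seq_len(dim(data)[1]))
  metadata <- as.data.frame(metadata)
  if (nrow(metadata) != dim(data)[1])
    stop("metadata rows must match trial count")
  structure(list(data = data, times = as.numeric(times), srate = srate,
                 labels = as.character(labels), metadata = metadata,
                 csd = isTRUE(csd)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$srate, " Hz [",
      round(min(x$times)), ", ", round(max(x$times)), "] ms",
      if (x$csd) " (CSD)" else "", "\n", sep = "")
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

CONTAINER_VERSION <- 1L

#' Save / load epoch containers
#'
#' Lossless, versioned, checksummed round-trip of an [eeg_epochs] object
#' (array, time axis, labels, sampling rate, per-trial metadata, CSD flag).
#'
#' @param ep an [eeg_epochs].
#' @param path file path for the container.
#' @return `save_epochs` returns `path` invisibly; `load_epochs` returns the
#'   restored [eeg_epochs].
#' @export
save_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "eeg_epochs"))
  payload <- unclass(ep)
  saveRDS(list(container = "motoreeg-epochs",
               version = CONTAINER_VERSION,
               checksum = digest::digest(payload, algo = "sha1"),
               payload = payload),
          path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable epoch container (",
                                           conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$container, "motoreeg-epochs"))
    stop("not a motoreeg epoch container")
  if (!identical(obj$version, CONTAINER_VERSION))
    stop("container version mismatch: file has ", obj$version,
         ", reader expects ", CONTAINER_VERSION)
  if (!identical(obj$checksum, digest::digest(obj$payload, algo = "sha1")))
    stop("checksum failure: epoch container is corrupt")
  p <- obj$payload
  eeg_epochs(p$data, p$times, p$srate, p$labels, p$metadata, p$csd)
}
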