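#' Raw multichannel recordings
#'
#' An `eeg_raw` is a channels x samples voltage matrix (microvolts) with a
#' sampling rate and a list of trigger events. Events mark button presses;
#' epoching is locked to them.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param srate sampling rate in Hz.
#' @param events data.frame with integer column `sample` (1-based sample
#'   index of the event onset) and column `code`.
#' @param labels channel labels (default Ch1..ChN).
#' @return An object of class `eeg_raw`.
#' @export
eeg_raw <- function(data, srate, events = data.frame(sample = integer(),
                                                     code = integer()),
                    labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("raw data contains non-finite samples")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("sampling rate must be a positive scalar")
  if (is.null(labels)) labels <- paste0("Ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("label count does not match channel count")
  events <- as.data.frame(events)
  if (!all(c("sample", "code") %in% names(events)))
    stop("events must have columns `sample` and `code`")
  if (nrow(events) > 0 &&
      (any(events$sample < 1L) || any(events$sample > ncol(data))))
    stop("event sample indices outside the record")
  rownames(data) <- labels
  structure(list(data = data, srate = srate, events = events,
                 labels = as.character(labels)),
            class = "eeg_raw")
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat("<eeg_raw> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$srate, " Hz, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

n_channels <- function(x) nrow(x$data)
n_samples_raw <- function(x) ncol(x$data)
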