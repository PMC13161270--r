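#' Optional continuous-data preprocessing
#'
#' Mirrors the standard continuous-EEG steps that precede epoching:
#' downsampling to `target_rate`, a zero-phase high-pass filter, bad-channel
#' interpolation, and re-referencing to the common average. Component-based
#' artifact decomposition (ICA and classifier-driven component removal) is
#' deliberately not included; run an external decomposition and pass its
#' result in, or rely on the threshold rejection in [reject_trials()].
#'
#' @param data channels x time numeric matrix (microvolts).
#' @param sample_rate input rate, Hz.
#' @param target_rate output rate, Hz; must divide `sample_rate` (no-op when
#'   equal).
#' @param highpass_hz high-pass cutoff, Hz (2nd-order Butterworth applied
#'   forward and backward; 0 disables).
#' @param average_reference re-reference to the mean over channels.
#' @param bad_channels labels to interpolate.
#' @param neighbors named list mapping a bad channel to the labels used for
#'   its interpolation (unweighted mean); defaults to all other channels.
#' @param channels channel labels (defaults to rownames).
#' @return list `data` (channels x time), `sample_rate`, `channels`.
#' @export
preprocess_continuous <- function(data, sample_rate, target_rate = 250,
                                  highpass_hz = 0.1, average_reference = TRUE,
                                  bad_channels = NULL, neighbors = NULL,
                                  channels = rownames(data)) {
  stopifnot(is.matrix(data), sample_rate >= target_rate)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))

  if (sample_rate != target_rate) {
    q <- sample_rate / target_rate
    if (abs(q - round(q)) > 1e-9)
      stop("target_rate must divide sample_rate", call. = FALSE)
    data <- t(apply(data, 1, signal::decimate, q = round(q)))
    sample_rate <- target_rate
  }

  if (highpass_hz > 0) {
    bf <- signal::butter(2, highpass_hz / (sample_rate / 2), type = "high")
    data <- t(apply(data, 1, function(x) signal::filtfilt(bf, x)))
  }

  for (bc in bad_channels) {
    i <- match(bc, channels)
    if (is.na(i)) stop("unknown bad channel: ", bc, call. = FALSE)
    nb <- neighbors[[bc]]
    if (is.null(nb)) nb <- setdiff(channels, bc)
    j <- match(nb, channels)
    if (anyNA(j)) stop("unknown neighbor channel(s) for ", bc, call. = FALSE)
    data[i, ] <- colMeans(data[j, , drop = FALSE])
  }

  if (average_reference) data <- sweep(data, 2, colMeans(data))
  rownames(data) <- channels
  list(data = data, sample_rate = sample_rate, channels = channels)
}
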