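#' Movement-locked epoch container
#'
#' Holds a trials x channels x time array of movement-locked EEG (microvolts),
#' its time axis in ms relative to movement onset (0 = onset), channel labels,
#' sampling rate, the original acquisition trial indices, and a per-trial
#' rejection mask with reasons.
#'
#' @param data numeric array, trials x channels x time.
#' @param times ms time axis, strictly increasing, length = dim 3.
#' @param channels unique channel labels, length = dim 2.
#' @param sample_rate Hz.
#' @param condition,participant metadata labels.
#' @param trial_index original acquisition indices (length = dim 1).
#' @param rejected logical mask, length = dim 1.
#' @param reject_reason character, length = dim 1.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, channels, sample_rate,
                      condition = NA_character_, participant = NA_character_,
                      trial_index = seq_len(dim(data)[1]),
                      rejected = rep(FALSE, dim(data)[1]),
                      reject_reason = rep(NA_character_, dim(data)[1])) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(channels),
            dim(data)[3] == length(times),
            length(trial_index) == dim(data)[1],
            length(rejected) == dim(data)[1],
            all(diff(times) > 0),
            !anyDuplicated(channels),
            sample_rate > 0)
  structure(list(data = data, times = times, channels = channels,
                 sample_rate = sample_rate, condition = condition,
                 participant = participant, trial_index = trial_index,
                 rejected = rejected, reject_reason = reject_reason),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples (%g Hz), %d to %d ms\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sample_rate,
    min(x$times), max(x$times)))
  cat(sprintf("  participant %s, condition %s; %d rejected\n",
              x$participant, x$condition, sum(x$rejected)))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

subset_epochs <- function(ep, idx) {
  epoch_set(ep$data[idx, , , drop = FALSE], ep$times, ep$channels,
            ep$sample_rate, condition = ep$condition,
            participant = ep$participant,
            trial_index = ep$trial_index[idx],
            rejected = ep$rejected[idx],
            reject_reason = ep$reject_reason[idx])
}

#' Epoch a continuous recording around movement-onset markers
#'
#' Cuts one epoch per marker, sample-accurately aligned so the marker sample
#' is 0 ms. Markers too close to the recording edge for the requested window
#' are dropped with reason `"edge"` (reported in the `dropped` attribute).
#'
#' @param data channels x time numeric matrix (microvolts).
#' @param onsets marker positions in samples (1-based).
#' @param sample_rate Hz.
#' @param channels channel labels (defaults to rownames).
#' @param window ms pair relative to onset (default c(-2000, 500)).
#' @param condition,participant metadata labels.
#' @return an [epoch_set()]; attribute `dropped` is a tibble of dropped
#'   markers and reasons.
#' @export
epoch_continuous <- function(data, onsets, sample_rate,
                             channels = rownames(data),
                             window = c(-2000, 500),
                             condition = NA_character_,
                             participant = NA_character_) {
  stopifnot(is.matrix(data), length(window) == 2, window[1] < window[2])
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  lo <- round(window[1] * sample_rate / 1000)
  hi <- round(window[2] * sample_rate / 1000)
  times <- seq(lo, hi) * 1000 / sample_rate
  ok <- (onsets + lo) >= 1 & (onsets + hi) <= ncol(data)
  dropped <- tibble::tibble(onset = onsets[!ok],
                            reason = rep("edge", sum(!ok)))
  keep <- which(ok)
  arr <- array(NA_real_, dim = c(length(keep), nrow(data), length(times)))
  for (k in seq_along(keep))
    arr[k, , ] <- data[, (onsets[keep[k]] + lo):(onsets[keep[k]] + hi)]
  ep <- epoch_set(arr, times, channels, sample_rate,
                  condition = condition, participant = participant,
                  trial_index = keep)
  attr(ep, "dropped") <- dropped
  ep
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window. The default window [-2000, -1500) ms precedes the analyzed
#' pre-movement period (target onset sits near -2000 ms), so the analysis
#' windows are referenced to pre-target activity. After correction the
#' baseline-window mean is zero to numerical precision; adding a constant
#' offset to an epoch leaves the corrected output unchanged.
#'
#' @param ep an [epoch_set()].
#' @param baseline ms pair; must lie within the epoch.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(ep, baseline = c(-2000, -1500)) {
  mask <- window_mask(ep$times, baseline)
  if (!any(mask) || baseline[1] < min(ep$times) || baseline[2] > max(ep$times) + 1e-9)
    stop("baseline window outside epoch", call. = FALSE)
  d <- dim(ep$data)
  m <- matrix(ep$data, nrow = d[1] * d[2])   # rows = trial x channel
  bl <- rowMeans(m[, mask, drop = FALSE])
  ep$data <- array(m - bl, dim = d)
  ep
}

#' Threshold-based trial rejection
#'
#' Flags trials whose peak-to-peak amplitude on any region-of-interest channel
#' exceeds `abs_threshold` (reason `"amplitude"`) or falls below
#' `flat_threshold` (reason `"flat"`). This is the package's stand-in for
#' manual inspection plus component-based artifact removal; an external
#' decomposition can be plugged in by pre-setting the `rejected` mask before
#' calling the rest of the pipeline.
#'
#' @param ep an [epoch_set()].
#' @param abs_threshold peak-to-peak ceiling, microvolts (> 0).
#' @param flat_threshold peak-to-peak floor, microvolts (> 0).
#' @param roi channels checked (default: all present ROI channels).
#' @return the `epoch_set` with its mask updated; attribute `rejection` is a
#'   one-row tibble (`n_total`, `n_rejected`, `retained_pct`). If every trial
#'   is rejected a warning flags the participant.
#' @export
reject_trials <- function(ep, abs_threshold = 150, flat_threshold = 0.5,
                          roi = NULL) {
  stopifnot(abs_threshold > 0, flat_threshold > 0)
  if (is.null(roi)) roi <- ep$channels
  ci <- match(roi, ep$channels)
  if (anyNA(ci)) stop("unknown ROI channel(s): ",
                      paste(roi[is.na(ci)], collapse = ", "), call. = FALSE)
  sub <- ep$data[, ci, , drop = FALSE]
  ds <- dim(sub)
  m <- matrix(sub, nrow = ds[1] * ds[2])    # rows = trial x channel
  ptp <- matrix(apply(m, 1, max) - apply(m, 1, min), nrow = ds[1])
  too_big <- apply(ptp, 1, max) > abs_threshold
  too_flat <- apply(ptp, 1, max) < flat_threshold
  new_rej <- (too_big | too_flat) & !ep$rejected
  ep$reject_reason[new_rej & too_big] <- "amplitude"
  ep$reject_reason[new_rej & too_flat] <- "flat"
  ep$rejected <- ep$rejected | too_big | too_flat
  n_tot <- n_trials(ep)
  attr(ep, "rejection") <- tibble::tibble(
    n_total = n_tot, n_rejected = sum(ep$rejected),
    retained_pct = retained_percentage(n_tot, sum(ep$rejected)))
  if (all(ep$rejected))
    warning("all trials rejected for participant ", ep$participant,
            call. = FALSE)
  ep
}

#' Retained-trial percentage
#'
#' The study's rejection-accounting formula: percentage of trials retained
#' given a (possibly fractional, e.g. cohort-mean) number rejected out of a
#' total. `retained_percentage(200, 23.90)` is exactly 88.05.
#'
#' @param n_total trials per participant.
#' @param n_rejected number (or cohort mean) rejected.
#' @return percentage in [0, 100].
#' @export
retained_percentage <- function(n_total, n_rejected) {
  stopifnot(n_total > 0, n_rejected >= 0, n_rejected <= n_total)
  100 * (n_total - n_rejected) / n_total
}

#' Region-of-interest average waveform
#'
#' Unweighted mean over the ROI channels, per trial and time point. The
#' default ROI is the midfrontal/central cluster F3, Fz, FC1, C3, Cz. Montages
#' that lack a requested channel but carry a listed alias (by default
#' FC1 -> FC3, reflecting a montage that records FC3 at that site) are
#' resolved with a loud warning; a missing channel with no alias is an error
#' naming the label.
#'
#' @param ep an [epoch_set()].
#' @param roi ROI channel labels.
#' @param aliases named character vector, `c(requested = substitute)`.
#' @return trials x time matrix with attributes `times`, `rejected`,
#'   `trial_index`.
#' @export
roi_average <- function(ep, roi = c("F3", "Fz", "FC1", "C3", "Cz"),
                        aliases = c(FC1 = "FC3")) {
  resolved <- vapply(roi, function(ch) {
    if (ch %in% ep$channels) return(ch)
    al <- aliases[ch]
    if (!is.na(al) && al %in% ep$channels) {
      warning("ROI channel ", ch, " absent from montage; using alias ", al,
              call. = FALSE)
      return(unname(al))
    }
    NA_character_
  }, character(1))
  if (anyNA(resolved))
    stop("ROI channel(s) missing with no alias: ",
         paste(roi[is.na(resolved)], collapse = ", "), call. = FALSE)
  ci <- match(resolved, ep$channels)
  d <- dim(ep$data)
  # channel-first layout lets colMeans average over the ROI in one pass
  out <- colMeans(aperm(ep$data[, ci, , drop = FALSE], c(2, 1, 3)))
  out <- matrix(out, nrow = d[1])
  structure(out, times = ep$times, rejected = ep$rejected,
            trial_index = ep$trial_index)
}

#' Split an epoch set into early and late halves
#'
#' Splits at the median original trial index of the condition: trials are
#' ordered by acquisition index and the first `ceiling(n/2)` form the early
#' half (so 7 trials split 4/3). Rejected trials count toward the positional
#' boundary but keep their rejected flag, so they never contribute to means.
#'
#' @param ep an [epoch_set()].
#' @return list with `early` and `late` `epoch_set`s.
#' @export
split_stages <- function(ep) {
  ord <- order(ep$trial_index)
  n <- length(ord)
  n_early <- ceiling(n / 2)
  list(early = subset_epochs(ep, ord[seq_len(n_early)]),
       late = subset_epochs(ep, ord[seq(n_early + 1, length.out = n - n_early)]))
}

#' Component mean amplitudes from ROI waveforms
#'
#' Averages the non-rejected trials into a single waveform, then takes the
#' mean amplitude within each component window. Windows are closed-open at
#' shared boundaries; only the window with the largest upper bound (MP) is
#' upper-inclusive.
#'
#' @param w trials x time matrix from [roi_average()] (or any matrix with a
#'   `times` attribute).
#' @param windows named list of ms pairs (default [component_windows()]).
#' @param times,rejected overrides for the matrix attributes.
#' @return one-row tibble `rp_mean`, `ns_mean`, `mp_mean` (or `<name>_mean`
#'   per window), plus `n_trials_used`; all means `NA` when no usable trial.
#' @export
component_means <- function(w, windows = component_windows(),
                            times = attr(w, "times"),
                            rejected = attr(w, "rejected")) {
  stopifnot(!is.null(times), ncol(w) == length(times))
  if (is.null(rejected)) rejected <- rep(FALSE, nrow(w))
  use <- which(!rejected)
  uppers <- vapply(windows, function(x) x[2], numeric(1))
  vals <- lapply(seq_along(windows), function(i) {
    if (!length(use)) return(NA_real_)
    avg <- colMeans(w[use, , drop = FALSE])
    mask <- window_mask(times, windows[[i]],
                        close_upper = uppers[i] == max(uppers))
    mean(avg[mask])
  })
  names(vals) <- paste0(names(windows), "_mean")
  dplyr::bind_cols(tibble::as_tibble(vals),
                   tibble::tibble(n_trials_used = length(use)))
}

#' Full MRP extraction for one epoch set
#'
#' Chains the pipeline: baseline correction, threshold rejection, early/late
#' split, ROI averaging, and component-window means.
#'
#' @param ep a raw [epoch_set()].
#' @param baseline baseline window (ms pair).
#' @param abs_threshold,flat_threshold rejection thresholds (microvolts).
#' @param roi,aliases see [roi_average()].
#' @param windows component windows.
#' @return tibble, one row per stage: `participant`, `condition`, `stage`,
#'   the component means, `n_trials_used`.
#' @export
extract_mrp <- function(ep, baseline = c(-2000, -1500),
                        abs_threshold = 150, flat_threshold = 0.5,
                        roi = c("F3", "Fz", "FC1", "C3", "Cz"),
                        aliases = c(FC1 = "FC3"),
                        windows = component_windows()) {
  ep <- baseline_correct(ep, baseline)
  ep <- reject_trials(ep, abs_threshold, flat_threshold,
                      roi = resolve_roi(ep$channels, roi, aliases))
  halves <- split_stages(ep)
  out <- lapply(names(halves), function(st) {
    w <- suppressWarnings(roi_average(halves[[st]], roi = roi, aliases = aliases))
    cm <- component_means(w, windows = windows)
    dplyr::bind_cols(tibble::tibble(participant = ep$participant,
                                    condition = ep$condition, stage = st), cm)
  })
  dplyr::bind_rows(out)
}

resolve_roi <- function(channels, roi, aliases) {
  out <- vapply(roi, function(ch) {
    if (ch %in% channels) ch
    else if (!is.na(aliases[ch]) && aliases[ch] %in% channels) unname(aliases[ch])
    else NA_character_
  }, character(1))
  out[!is.na(out)]
}

#' Grand-average ROI waveform table
#'
#' Per-trial ROI waveforms averaged over non-rejected trials of each epoch
#' set, returned long for plotting/export.
#'
#' @param epochs named list of [epoch_set()]s (`"<participant>.<condition>"`).
#' @param baseline baseline window applied before averaging.
#' @param roi,aliases see [roi_average()].
#' @return tibble `participant`, `condition`, `time_ms`, `amplitude_uv`.
#' @export
grand_average <- function(epochs, baseline = c(-2000, -1500),
                          roi = c("F3", "Fz", "FC1", "C3", "Cz"),
                          aliases = c(FC1 = "FC3")) {
  rows <- lapply(epochs, function(ep) {
    ep <- baseline_correct(ep, baseline)
    w <- suppressWarnings(roi_average(ep, roi = roi, aliases = aliases))
    use <- !ep$rejected
    tibble::tibble(participant = ep$participant, condition = ep$condition,
                   time_ms = ep$times,
                   amplitude_uv = colMeans(w[use, , drop = FALSE]))
  })
  dplyr::bind_rows(rows)
}
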