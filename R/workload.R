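#' Raw NASA-TLX overall score
#'
#' Unweighted ("raw TLX") mean of the six dimension scores, mapped linearly
#' from the 21-point 0-20 response scale to 0-100 (0, 5, ..., 100). No
#' pairwise-comparison weights are collected or applied.
#'
#' @param scores numeric vector or one-row data frame of the six dimension
#'   scores (`mental`, `physical`, `temporal`, `performance`, `effort`,
#'   `frustration`) on the 0-20 scale.
#' @param scale_max top of the response scale (default 20).
#' @return overall workload on 0-100, or `NA` if any dimension is missing.
#' @export
tlx_overall <- function(scores, scale_max = 20) {
  v <- tlx_vector(scores)
  if (anyNA(v)) return(NA_real_)
  mean(v) * 100 / scale_max
}

#' NASA-TLX subscales
#'
#' Task-related = mean(mental, physical, temporal); behavior-related =
#' mean(performance, effort). Frustration enters neither subscale. Scores are
#' rescaled to 0-100 like [tlx_overall()].
#'
#' @inheritParams tlx_overall
#' @return named list `task_related`, `behavior_related` (0-100).
#' @export
tlx_subscales <- function(scores, scale_max = 20) {
  v <- tlx_vector(scores)
  sc <- 100 / scale_max
  task <- v[c("mental", "physical", "temporal")]
  beh <- v[c("performance", "effort")]
  list(task_related = if (anyNA(task)) NA_real_ else mean(task) * sc,
       behavior_related = if (anyNA(beh)) NA_real_ else mean(beh) * sc)
}

tlx_vector <- function(scores) {
  dims <- tlx_dimensions()
  if (is.data.frame(scores)) {
    stopifnot(nrow(scores) == 1)
    miss <- setdiff(dims, names(scores))
    if (length(miss)) stop("missing TLX dimension(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    v <- as.numeric(scores[1, dims])
  } else if (!is.null(names(scores))) {
    miss <- setdiff(dims, names(scores))
    if (length(miss)) stop("missing TLX dimension(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    v <- as.numeric(scores[dims])
  } else {
    stopifnot(length(scores) == 6)
    v <- as.numeric(scores)
  }
  if (any(v < 0 | v > 20, na.rm = TRUE))
    stop("TLX scores must lie on the 0-20 scale", call. = FALSE)
  names(v) <- dims
  v
}

#' Score a table of NASA-TLX responses
#'
#' @param tlx tibble with `participant`, `condition` and the six dimension
#'   columns (0-20 scale).
#' @return the input plus `overall`, `task_related`, `behavior_related`
#'   (0-100 scale).
#' @export
score_tlx <- function(tlx) {
  stopifnot(all(c("participant", "condition") %in% names(tlx)),
            all(tlx_dimensions() %in% names(tlx)))
  n <- nrow(tlx)
  overall <- task <- beh <- numeric(n)
  for (i in seq_len(n)) {
    row <- tlx[i, ]
    overall[i] <- tlx_overall(row)
    s <- tlx_subscales(row)
    task[i] <- s$task_related
    beh[i] <- s$behavior_related
  }
  tlx$overall <- overall
  tlx$task_related <- task
  tlx$behavior_related <- beh
  tlx
}
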