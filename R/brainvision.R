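#' Read a BrainVision recording
#'
#' Minimal reader for the BrainVision triplet (.vhdr header, .vmrk markers,
#' data file). Supports ASCII and binary (IEEE_FLOAT_32, INT_16) data in
#' MULTIPLEXED or VECTORIZED orientation, applying per-channel resolutions.
#'
#' @param vhdr path to the `.vhdr` header.
#' @return list with `data` (channels x time matrix, microvolts), `channels`,
#'   `sample_rate` (Hz), and `markers` (tibble `type`, `description`,
#'   `position` in samples).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  ini <- parse_ini(lines)
  ci <- ini[["Common Infos"]]
  n_ch <- as.integer(ci$NumberOfChannels)
  sample_rate <- 1e6 / as.numeric(ci$SamplingInterval)
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  format <- toupper(ci$DataFormat %||% "BINARY")

  ch_entries <- ini[["Channel Infos"]]
  ch_parts <- lapply(ch_entries[paste0("Ch", seq_len(n_ch))],
                     function(x) strsplit(x, ",", fixed = TRUE)[[1]])
  channels <- unname(vapply(ch_parts, `[`, character(1), 1))
  resolution <- unname(vapply(ch_parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1)))

  datafile <- file.path(dirname(vhdr), ci$DataFile)
  if (format == "ASCII") {
    raw <- data.table::fread(datafile, header = FALSE,
                             skip = as.integer(ini[["ASCII Infos"]]$SkipLines %||% 0))
    m <- as.matrix(raw)
    data <- if (orientation == "VECTORIZED") m else t(m)
  } else {
    bformat <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
    n_val <- file.size(datafile) /
      switch(bformat, IEEE_FLOAT_32 = 4L, INT_16 = 2L,
             stop("unsupported BinaryFormat: ", bformat, call. = FALSE))
    con <- file(datafile, "rb"); on.exit(close(con))
    v <- switch(bformat,
      IEEE_FLOAT_32 = readBin(con, "double", n = n_val, size = 4),
      INT_16 = readBin(con, "integer", n = n_val, size = 2, signed = TRUE))
    data <- if (orientation == "VECTORIZED")
      t(matrix(v, ncol = n_ch)) else matrix(v, nrow = n_ch)
  }
  data <- data * resolution
  rownames(data) <- channels

  markers <- tibble::tibble(type = character(), description = character(),
                            position = integer())
  vmrk <- file.path(dirname(vhdr), ci$MarkerFile %||% "")
  if (nzchar(ci$MarkerFile %||% "") && file.exists(vmrk)) {
    mk <- parse_ini(readLines(vmrk, warn = FALSE))[["Marker Infos"]]
    if (length(mk)) {
      parts <- lapply(mk, function(x) strsplit(x, ",", fixed = TRUE)[[1]])
      markers <- tibble::tibble(
        type = vapply(parts, `[`, character(1), 1),
        description = vapply(parts, `[`, character(1), 2),
        position = as.integer(vapply(parts, `[`, character(1), 3)))
    }
  }
  list(data = data, channels = channels, sample_rate = sample_rate,
       markers = markers)
}

#' Write a BrainVision recording (ASCII)
#'
#' Writes the `.vhdr`/`.vmrk`/`.dat` triplet in ASCII VECTORIZED layout (one
#' text line per channel), primarily for interoperability round-trips.
#'
#' @param data channels x time matrix (microvolts).
#' @param sample_rate Hz.
#' @param file_base path without extension.
#' @param channels channel labels (defaults to rownames).
#' @param markers optional tibble `type`, `description`, `position` (samples).
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(data, sample_rate, file_base,
                              channels = rownames(data), markers = NULL) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  base <- basename(file_base)
  vhdr <- paste0(file_base, ".vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".dat"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=ASCII",
    "DataOrientation=VECTORIZED",
    paste0("NumberOfChannels=", nrow(data)),
    paste0("SamplingInterval=", format(1e6 / sample_rate, scientific = FALSE)),
    "[ASCII Infos]",
    "SkipLines=0",
    "SkipColumns=0",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(data)), channels)), vhdr)
  data.table::fwrite(data.table::as.data.table(data), paste0(file_base, ".dat"),
                     sep = " ", col.names = FALSE)
  mk_lines <- c("Brain Vision Data Exchange Marker File, Version 1.0",
                "[Common Infos]", paste0("DataFile=", base, ".dat"),
                "[Marker Infos]")
  if (!is.null(markers) && nrow(markers))
    mk_lines <- c(mk_lines, sprintf("Mk%d=%s,%s,%d,1,0",
                                    seq_len(nrow(markers)), markers$type,
                                    markers$description, markers$position))
  writeLines(mk_lines, paste0(file_base, ".vmrk"))
  invisible(vhdr)
}

parse_ini <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  out <- list()
  section <- "top"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <-
        trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
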