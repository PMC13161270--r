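#' Write a cohort bundle to disk
#'
#' Plain-text layout: `participants.csv`, `trial_samples.csv` (long:
#' participant, trial, condition, target_deg, t, x_mm, y_mm), per
#' participant-and-condition epoch matrices (`epochs_<id>_<condition>.csv`,
#' rows = trial x channel, columns = samples) described by
#' `epochs_manifest.json` (channel names, sample rate, time-zero index, trial
#' indices), `tlx.csv`, `config.yaml`, and a run manifest with file digests.
#'
#' @param cohort a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  data.table::fwrite(cohort$participants, p("participants.csv"))
  data.table::fwrite(cohort$trials, p("trials.csv"))

  if (length(cohort$trajectories)) {
    samp <- lapply(names(cohort$trajectories), function(pid) {
      trs <- cohort$trajectories[[pid]]
      data.table::rbindlist(lapply(trs, function(tr) {
        data.table::data.table(
          participant = pid, trial_index = tr$trial_index,
          condition = tr$condition, target_deg = tr$target_deg,
          t = tr$t, x_mm = tr$x, y_mm = tr$y)
      }))
    })
    data.table::fwrite(data.table::rbindlist(samp), p("trial_samples.csv"))
  }

  if (length(cohort$epochs)) {
    manifest <- list()
    for (key in names(cohort$epochs)) {
      ep <- cohort$epochs[[key]]
      fn <- paste0("epochs_", gsub("[^A-Za-z0-9_.-]", "_", key), ".csv")
      d <- dim(ep$data)
      m <- matrix(aperm(ep$data, c(2, 1, 3)), nrow = d[1] * d[2])
      # rows ordered: trial 1 all channels, trial 2 all channels, ...
      data.table::fwrite(data.table::as.data.table(m), p(fn),
                         col.names = FALSE)
      manifest[[key]] <- list(
        file = fn, participant = ep$participant, condition = ep$condition,
        n_trials = d[1], channels = ep$channels,
        sample_rate = ep$sample_rate,
        time_zero_index = which.min(abs(ep$times)),
        times_ms = range(ep$times),
        trial_index = ep$trial_index, rejected = ep$rejected)
    }
    jsonlite::write_json(manifest, p("epochs_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (!is.null(cohort$tlx)) data.table::fwrite(cohort$tlx, p("tlx.csv"))
  write_config(cohort$config, p("config.yaml"))
  write_manifest(dir, seed = cohort$config$seed)
  invisible(dir)
}

#' Read a cohort bundle from disk
#'
#' Inverse of [write_cohort()]. Trajectories are rebuilt as `trajectory`
#' objects and epoch matrices as [epoch_set()]s from the JSON manifest.
#'
#' @param dir directory written by [write_cohort()].
#' @return a `cohort_bundle`.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- c("participants.csv", "trials.csv", "config.yaml")
  miss <- need[!file.exists(p(need))]
  if (length(miss))
    stop("incomplete cohort bundle; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  config <- read_config(p("config.yaml"))
  participants <- tibble::as_tibble(data.table::fread(p("participants.csv")))
  trials <- tibble::as_tibble(data.table::fread(p("trials.csv")))

  trajectories <- list()
  if (file.exists(p("trial_samples.csv"))) {
    samp <- data.table::fread(p("trial_samples.csv"))
    for (pid in unique(samp$participant)) {
      sp <- samp[samp$participant == pid, ]
      trajectories[[pid]] <- lapply(split(sp, by = "trial_index", sorted = TRUE),
        function(d) {
          structure(list(t = d$t, x = d$x_mm, y = d$y_mm, cue_time = 0,
                         target_deg = d$target_deg[1],
                         condition = d$condition[1],
                         trial_index = d$trial_index[1],
                         timeout_flag = NA), class = "trajectory")
        })
    }
  }

  epochs <- list()
  if (file.exists(p("epochs_manifest.json"))) {
    manifest <- jsonlite::read_json(p("epochs_manifest.json"),
                                    simplifyVector = TRUE)
    for (key in names(manifest)) {
      mf <- manifest[[key]]
      m <- as.matrix(data.table::fread(p(mf$file), header = FALSE))
      n_c <- length(mf$channels)
      n_s <- ncol(m)
      arr <- aperm(array(m, dim = c(n_c, mf$n_trials, n_s)), c(2, 1, 3))
      times <- seq(mf$times_ms[1], mf$times_ms[2],
                   length.out = n_s)
      epochs[[key]] <- epoch_set(arr, times, mf$channels, mf$sample_rate,
                                 condition = mf$condition,
                                 participant = mf$participant,
                                 trial_index = mf$trial_index,
                                 rejected = mf$rejected)
    }
  }

  tlx <- if (file.exists(p("tlx.csv")))
    tibble::as_tibble(data.table::fread(p("tlx.csv"))) else NULL

  structure(list(config = config, participants = participants,
                 trials = trials, trajectories = trajectories,
                 epochs = epochs, tlx = tlx),
            class = "cohort_bundle")
}

#' Write a run manifest
#'
#' JSON record sufficient to re-run identically: package version, timestamp,
#' seed, and an MD5 digest of every file in the directory.
#'
#' @param dir directory to fingerprint.
#' @param seed the RNG seed of the run.
#' @param extra optional named list merged into the manifest.
#' @return manifest list, invisibly.
#' @export
write_manifest <- function(dir, seed = NA_integer_, extra = list()) {
  files <- setdiff(list.files(dir), "run_manifest.json")
  digests <- tools::md5sum(file.path(dir, files))
  names(digests) <- files
  manifest <- c(list(
    package = "readyset",
    version = as.character(utils::packageVersion("readyset")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    files = as.list(digests)), extra)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write study results to disk
#'
#' Tidy CSVs (trial table, cleaning report, MRP components, rejection
#' accounting, TLX scores, demographics, per-model ANOVA and pairwise tables,
#' grand-average waveforms) plus a human-readable `report.md`.
#'
#' @param results a `study_results` from [run_study()].
#' @param dir output directory.
#' @param waveforms optional tibble from [grand_average()].
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(results, dir, waveforms = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  data.table::fwrite(results$trial_table, p("trial_table.csv"))
  data.table::fwrite(results$cleaning_report, p("cleaning_report.csv"))
  if (!is.null(results$mrp)) data.table::fwrite(results$mrp, p("mrp_components.csv"))
  if (!is.null(results$rejection))
    data.table::fwrite(results$rejection, p("rejection_summary.csv"))
  if (!is.null(results$tlx)) data.table::fwrite(results$tlx, p("tlx_scores.csv"))
  data.table::fwrite(results$demographics, p("demographics.csv"))
  anovas <- dplyr::bind_rows(lapply(results$models, `[[`, "anova"),
                             .id = "measure")
  data.table::fwrite(anovas, p("model_anovas.csv"))
  pw <- dplyr::bind_rows(lapply(results$models, `[[`, "pairwise"),
                         .id = "measure")
  data.table::fwrite(pw, p("model_pairwise.csv"))
  if (!is.null(waveforms))
    data.table::fwrite(waveforms, p("grand_average_waveforms.csv"))
  writeLines(render_report(results), p("report.md"))
  invisible(dir)
}

render_report <- function(results) {
  out <- c("# Study analysis report", "",
           "Models: linear mixed effects (REML, sum-to-zero contrasts,",
           "random intercept per participant, Satterthwaite df); pairwise",
           "contrasts: Sidak-adjusted estimated marginal means; effect size:",
           "mean difference / total model SD.", "", "## Demographics", "")
  d <- results$demographics
  out <- c(out, sprintf("- %s: t(%d) = %.3f, p = %.3g, d = %.3f, MD = %.3f",
                        d$measure, d$df, d$t, d$p, d$cohens_d, d$md))
  if (!is.null(results$rejection)) {
    out <- c(out, "", "## Epoch rejection", "")
    r <- results$rejection
    out <- c(out, sprintf(
      "- %s: mean %.2f of %d trials rejected, resulting in %.2f%% trials being retained",
      r$condition, r$mean_rejected, r$n_total, r$retained_pct))
  }
  for (nm in names(results$models)) {
    a <- results$models[[nm]]$anova
    out <- c(out, "", paste0("## ", nm), "")
    out <- c(out, sprintf("- %s: F(%g, %.3f) = %.3f, p = %.3g",
                          a$effect, a$df1, a$df2, a$F, a$p))
  }
  out
}
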