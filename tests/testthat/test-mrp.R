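# Epoching, baseline correction, rejection, ROI averaging, stage splitting,
# component means.

test_that("epoching recovers a template inserted at each marker", {
  set.seed(2)
  sr <- 250
  n_time <- 5000
  tpl_times <- seq(-500, 500, by = 1000 / sr)
  tpl <- sin(seq(0, 2 * pi, length.out = length(tpl_times)))
  cont <- matrix(rnorm(2 * n_time, 0, 0.1), nrow = 2)
  onsets <- c(400, 1500, 2600, 3700)
  lo <- round(-500 * sr / 1000)
  for (on in onsets)
    cont[, (on + lo):(on + lo + length(tpl) - 1)] <-
      cont[, (on + lo):(on + lo + length(tpl) - 1)] +
      rep(tpl, each = 2)
  ep <- epoch_continuous(cont, onsets, sr, channels = c("Cz", "Pz"),
                         window = c(-500, 500))
  expect_equal(dim(ep$data), c(4, 2, length(tpl)))
  avg <- apply(ep$data, 3, mean)
  expect_equal(avg, tpl, tolerance = 0.2)
  expect_equal(ep$times[which.min(abs(ep$times))], 0)
})

test_that("markers too close to the recording edge are dropped", {
  cont <- matrix(0, 1, 1000)
  sr <- 250
  # 100 ms from start with a 2000 ms pre-window: dropped with reason edge
  ep <- epoch_continuous(cont, c(25, 600), sr, window = c(-2000, 500))
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(attr(ep, "dropped")$reason, "edge")
  expect_equal(attr(ep, "dropped")$onset, 25)
})

test_that("constant channels yield constant epochs", {
  cont <- matrix(7, 2, 2000)
  ep <- epoch_continuous(cont, c(600, 1200), 250, window = c(-1000, 500))
  expect_true(all(ep$data == 7))
})

test_that("baseline correction zeroes the baseline window and kills offsets", {
  set.seed(6)
  wave <- rnorm(626)
  ep <- waveform_epochs(wave)
  bc <- baseline_correct(ep)
  mask <- bc$times >= -2000 & bc$times < -1500
  expect_equal(max(abs(apply(bc$data[, , mask, drop = FALSE], c(1, 2), mean))),
               0, tolerance = 1e-12)
  # offset invariance
  ep2 <- ep
  ep2$data <- ep2$data + 42
  bc2 <- baseline_correct(ep2)
  expect_equal(bc2$data, bc$data, tolerance = 1e-12)
  # window outside the epoch errors
  expect_error(baseline_correct(ep, c(-3000, -2500)), "outside")
})

test_that("ramp epochs correct to the template minus its analytic baseline mean", {
  times <- seq(-2000, 500, by = 4)
  ramp <- (times + 2000) / 2500          # 0 at -2000 rising to 1
  ep <- waveform_epochs(ramp)
  bc <- baseline_correct(ep)
  bl_mean <- mean(ramp[times >= -2000 & times < -1500])
  expect_equal(bc$data[1, 1, ], ramp - bl_mean, tolerance = 1e-12)
})

test_that("threshold rejection flags large and flat trials with reasons", {
  times <- seq(-2000, 500, by = 4)
  wave <- sin(times / 100) * 5
  ep <- waveform_epochs(wave, n_trials = 6)
  ep$data[2, , 100] <- 400                 # amplitude artifact
  ep$data[5, , ] <- 0.01                   # flat trial
  out <- reject_trials(ep, abs_threshold = 150, flat_threshold = 0.5)
  expect_equal(which(out$rejected), c(2L, 5L))
  expect_equal(out$reject_reason[2], "amplitude")
  expect_equal(out$reject_reason[5], "flat")
  expect_equal(attr(out, "rejection")$retained_pct, 100 * 4 / 6)
  # clean epochs, generous threshold: none rejected
  ep2 <- waveform_epochs(wave, n_trials = 4)
  expect_equal(sum(reject_trials(ep2, 1000, 0.1)$rejected), 0)
  # all rejected: participant flagged
  ep3 <- waveform_epochs(rep(0.001, length(times)), n_trials = 3)
  expect_warning(reject_trials(ep3, 150, 0.5), "all trials rejected")
})

test_that("simulated artifact rate is recovered by rejection", {
  cfg <- cohort_config(artifact_rate = 0.1, seed = 1)
  set.seed(8)
  ep <- simulate_epochs(cfg, "control", "adaptation", 400)
  out <- reject_trials(baseline_correct(ep), abs_threshold = 150,
                       flat_threshold = 0.5, roi = cfg$roi_channels)
  rate <- mean(out$rejected)
  se <- sqrt(0.1 * 0.9 / 400)
  expect_lt(abs(rate - 0.1), 3 * se)
})

test_that("retained percentage follows the accounting formula exactly", {
  expect_equal(retained_percentage(200, 23.90), 88.05)
  expect_equal(retained_percentage(200, 0), 100)
  expect_error(retained_percentage(200, 300))
})

test_that("ROI averaging is an unweighted channel mean with alias fallback", {
  times <- seq(-2000, 500, by = 4)
  ep <- waveform_epochs(rep(0, length(times)), n_trials = 2,
                        channels = c("F3", "Fz", "FC3", "C3", "Cz"))
  ep$data[, 1, ] <- 1                     # F3 = 1, others 0 -> mean 0.2
  expect_warning(w <- roi_average(ep), "FC1.*FC3")
  expect_true(all(abs(w - 0.2) < 1e-12))
  # identical channels: average equals any one of them
  ep2 <- waveform_epochs(sin(times / 200), n_trials = 3,
                         channels = c("F3", "Fz", "FC3", "C3", "Cz"))
  w2 <- suppressWarnings(roi_average(ep2))
  expect_equal(unname(w2[2, ]), ep2$data[2, 1, ])
  # missing channel with no alias errors with the label
  ep3 <- waveform_epochs(rep(0, length(times)), channels = c("F3", "Fz", "C3", "Cz", "Pz"))
  expect_error(suppressWarnings(roi_average(ep3)), "FC1")
})

test_that("ROI average equals a brute-force per-sample mean", {
  set.seed(14)
  arr <- array(rnorm(5 * 7 * 100), dim = c(5, 7, 100))
  ep <- epoch_set(arr, times = seq(-200, 196, by = 4),
                  channels = c("F3", "Fz", "FC3", "C3", "Cz", "Pz", "Oz"),
                  sample_rate = 250)
  w <- suppressWarnings(roi_average(ep))
  for (tr in 1:5) for (s in sample(100, 10))
    expect_equal(w[tr, s], mean(arr[tr, 1:5, s]))
})

test_that("stage split halves by original trial index with documented ties", {
  times <- seq(-2000, 500, by = 4)
  ep <- waveform_epochs(rep(0, length(times)), n_trials = 7)
  halves <- split_stages(ep)
  expect_equal(dim(halves$early$data)[1], 4)
  expect_equal(dim(halves$late$data)[1], 3)
  expect_equal(halves$early$trial_index, 1:4)
  # 200 trials, none rejected: 100/100
  ep2 <- waveform_epochs(rep(0, length(times)), n_trials = 200)
  halves2 <- split_stages(ep2)
  expect_equal(dim(halves2$early$data)[1], 100)
  # rejected trials keep their positional slot but not membership in means
  ep3 <- waveform_epochs(rep(1, length(times)), n_trials = 10)
  ep3$rejected[1:3] <- TRUE
  halves3 <- split_stages(ep3)
  expect_equal(halves3$early$trial_index, 1:5)
  cm <- component_means(suppressWarnings(roi_average(halves3$early)))
  expect_equal(cm$n_trials_used, 2)
})

test_that("component means integrate windows with declared boundary ownership", {
  times <- seq(-2000, 500, by = 4)
  # arbitrary smooth waveform vs independent numeric quadrature
  wave <- 3 * sin(times / 300) - 2 * exp(-(times + 300)^2 / 1e5)
  ep <- waveform_epochs(wave)
  cm <- component_means(suppressWarnings(roi_average(ep)))
  for (nm in c("rp", "ns", "mp")) {
    win <- component_windows()[[nm]]
    mask <- if (nm == "mp") times >= win[1] & times <= win[2]
            else times >= win[1] & times < win[2]
    expect_equal(cm[[paste0(nm, "_mean")]], mean(wave[mask]))
    # quadrature cross-check over the half-open sample span (4 ms grid step)
    f <- approxfun(times, wave)
    hi <- if (nm == "mp") win[2] else win[2] - 4
    g <- seq(win[1], hi, length.out = 4001)
    quad <- mean(f(g))
    expect_lt(abs(cm[[paste0(nm, "_mean")]] - quad), 0.02)
  }
  # shared boundary samples belong to the later window
  spike <- rep(0, length(times)); spike[times == -500] <- 100
  cms <- component_means(suppressWarnings(roi_average(waveform_epochs(spike))))
  expect_equal(cms$rp_mean, 0)
  expect_gt(cms$ns_mean, 0)
})

test_that("component means are linear in the epochs", {
  set.seed(21)
  times <- seq(-2000, 500, by = 4)
  a <- waveform_epochs(rnorm(length(times)))
  b <- waveform_epochs(rnorm(length(times)))
  mix <- a; mix$data <- (a$data + b$data) / 2
  cm_mix <- component_means(suppressWarnings(roi_average(mix)))
  cm_a <- component_means(suppressWarnings(roi_average(a)))
  cm_b <- component_means(suppressWarnings(roi_average(b)))
  for (nm in c("rp_mean", "ns_mean", "mp_mean"))
    expect_equal(cm_mix[[nm]], (cm_a[[nm]] + cm_b[[nm]]) / 2, tolerance = 1e-12)
})

test_that("baseline correction and ROI averaging commute", {
  set.seed(25)
  arr <- array(rnorm(3 * 5 * 626), dim = c(3, 5, 626))
  ep <- epoch_set(arr, times = seq(-2000, 500, by = 4),
                  channels = c("F3", "Fz", "FC3", "C3", "Cz"),
                  sample_rate = 250)
  w1 <- suppressWarnings(roi_average(baseline_correct(ep)))
  w2 <- suppressWarnings(roi_average(ep))
  mask <- ep$times >= -2000 & ep$times < -1500
  w2c <- w2 - rowMeans(w2[, mask])
  expect_equal(unclass(w1), unclass(w2c), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-noise pipeline returns template window means exactly", {
  cfg <- tiny_zero_cfg(seed = 10)
  co <- simulate_cohort(cfg, what = "eeg")
  mrp <- dplyr::bind_rows(lapply(co$epochs, extract_mrp))
  times <- seq(-2000, 500, by = 4)
  w <- component_windows()
  for (r in sample(nrow(mrp), 8)) {
    grp <- co$participants$group[co$participants$participant == mrp$participant[r]]
    tpl <- mrp_template(times, cfg, grp, mrp$condition[r], mrp$stage[r])
    expect_equal(mrp$rp_mean[r], mean(tpl[times >= -1500 & times < -500]),
                 tolerance = 1e-10)
    expect_equal(mrp$ns_mean[r], mean(tpl[times >= -500 & times < -100]),
                 tolerance = 1e-10)
    expect_equal(mrp$mp_mean[r], mean(tpl[times >= -100 & times <= 100]),
                 tolerance = 1e-10)
  }
})
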