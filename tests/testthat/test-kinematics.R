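# Behavioral measures: response time, sample cleaning, peak velocity and its
# cleaning cascade, circular hand angle, stage summaries.

test_that("response time is the first threshold crossing after the cue", {
  # 1 mm per 10 ms sample: 10 mm is reached at the 10th sample = 0.100 s
  t <- seq(0, 0.2, by = 0.01)
  tr <- structure(list(t = t, x = t * 100, y = rep(0, length(t)),
                       cue_time = 0), class = "trajectory")
  expect_equal(response_time(tr), 0.100)
  # never crossing: flagged missing
  tr$x <- pmin(tr$x, 9.9)
  expect_true(is.na(response_time(tr)))
})

test_that("response time equals a brute-force scan on random trajectories", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    tr <- structure(list(t = cumsum(runif(n, 0.001, 0.01)),
                         x = cumsum(rnorm(n, 0.5, 1)),
                         y = cumsum(rnorm(n, 0.5, 1)),
                         cue_time = 0), class = "trajectory")
    oracle <- NA_real_
    for (k in seq_len(n)) {
      if (sqrt(tr$x[k]^2 + tr$y[k]^2) >= 10) { oracle <- tr$t[k]; break }
    }
    expect_identical(response_time(tr), oracle)
  }
})

test_that("sample cleaning removes frozen frames and spikes, and no more", {
  base <- line_trajectory(v = 300, t_max = 0.3)
  # equal successive steps: IQR = 0, nothing removed
  cl <- clean_samples(base)
  expect_equal(length(cl$t), length(base$t))
  expect_equal(attr(cl, "n_removed_duplicates") + attr(cl, "n_removed_iqr"), 0)
  # one frozen frame: exactly one duplicate removed
  frozen <- base
  frozen$x <- append(frozen$x, frozen$x[10], after = 10)
  frozen$y <- append(frozen$y, frozen$y[10], after = 10)
  frozen$t <- append(frozen$t, frozen$t[10] + 0.002, after = 10)
  cl2 <- clean_samples(frozen)
  expect_equal(attr(cl2, "n_removed_duplicates"), 1)
  expect_equal(length(cl2$t), length(base$t))
})

test_that("spike removal matches a brute-force reimplementation", {
  brute <- function(x, y, t, mult = 10) {
    dup <- c(FALSE, diff(x) == 0 & diff(y) == 0)
    x <- x[!dup]; y <- y[!dup]; t <- t[!dup]
    d <- sqrt(diff(x)^2 + diff(y)^2)
    iqr <- IQR(d)
    keep <- rep(TRUE, length(x))
    if (iqr > 0) for (k in 2:length(x)) if (d[k - 1] > mult * iqr) keep[k] <- FALSE
    list(x = x[keep], y = y[keep], t = t[keep])
  }
  set.seed(7)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n)); t <- seq_len(n) * 0.004
    if (i %% 2 == 0) x[sample(2:n, 1)] <- 10000   # inject a spike
    if (i %% 3 == 0) { j <- sample(2:n, 1); x[j] <- x[j - 1]; y[j] <- y[j - 1] }
    tr <- structure(list(t = t, x = x, y = y, cue_time = 0), class = "trajectory")
    cl <- clean_samples(tr)
    o <- brute(x, y, t)
    expect_equal(cl$x, o$x)
    expect_equal(cl$y, o$y)
  }
})

test_that("a huge spike is removed from a smooth path", {
  # smooth bell-speed reach: successive steps vary, so the IQR is informative
  t <- seq(0, 0.3, by = 0.004)
  u <- t / 0.3
  tr <- structure(list(t = t, x = 100 * (10 * u^3 - 15 * u^4 + 6 * u^5),
                       y = rep(0, length(t)), cue_time = 0),
                  class = "trajectory")
  tr$x[30] <- 10000
  cl <- clean_samples(tr)
  expect_true(all(abs(cl$x) < 5000))
  expect_gte(attr(cl, "n_removed_iqr"), 1)
})

test_that("cleaning is idempotent", {
  set.seed(11)
  for (i in 1:20) {
    n <- 30
    tr <- structure(list(t = seq_len(n) * 0.004, x = cumsum(rnorm(n)),
                         y = cumsum(rnorm(n)), cue_time = 0),
                    class = "trajectory")
    tr$x[12] <- 5000
    once <- clean_samples(tr)
    twice <- clean_samples(once)
    expect_equal(twice$x, once$x)
    expect_equal(attr(twice, "n_removed_duplicates") +
                   attr(twice, "n_removed_iqr"), 0)
  }
})

test_that("peak velocity recovers analytic speed profiles", {
  # constant 300 mm/s straight path
  tr <- line_trajectory(v = 300, t_max = 0.4)
  expect_equal(peak_velocity(tr), 300, tolerance = 1e-9)
  # triangular speed profile peaking at v_max: discrete estimate within one step
  dt <- 0.002; v_max <- 500; t <- seq(0, 0.2, by = dt)
  v <- v_max * (1 - abs(t - 0.1) / 0.1)
  x <- cumsum(c(0, (v[-1] + v[-length(v)]) / 2 * dt))
  tr2 <- structure(list(t = t, x = x, y = rep(0, length(t)), cue_time = 0),
                   class = "trajectory")
  step_err <- v_max * dt / 0.1
  expect_equal(peak_velocity(tr2), v_max, tolerance = step_err / v_max)
})

test_that("peak velocity is invariant under global rotation", {
  set.seed(3)
  tr <- line_trajectory(v = 350, t_max = 0.3)
  for (ang in c(13, 90, 211, -77)) {
    expect_equal(peak_velocity(rotate_traj(tr, ang)), peak_velocity(tr),
                 tolerance = 1e-12)
  }
})

test_that("peak-velocity cleaning cascade handles its edge cases", {
  # all equal: SD = 0, deviation 0 is not > 0, nothing removed
  r <- clean_peak_velocity(rep(500, 30))
  expect_equal(sum(r$keep), 30)
  # absolute cutoff fires before the SD rule
  r2 <- clean_peak_velocity(c(rep(500, 30), 2500))
  expect_equal(r2$report$n_removed_absolute, 1)
  expect_equal(r2$report$n_removed_3sd, 0)
  expect_true(is.na(r2$values[31]))
  expect_equal(r2$report$retained_fraction, 30 / 31)
})

test_that("peak-velocity cleaning matches a brute-force oracle", {
  brute <- function(v, cutoff = 2000, mult = 3) {
    keep <- rep(FALSE, length(v))
    surv <- c()
    for (k in seq_along(v)) if (is.finite(v[k]) && v[k] <= cutoff) surv <- c(surv, k)
    m <- mean(v[surv]); s <- sd(v[surv]); if (is.na(s)) s <- 0
    for (k in surv) if (abs(v[k] - m) <= mult * s) keep[k] <- TRUE
    keep
  }
  set.seed(19)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    v <- rlnorm(n, log(600), 0.4)
    if (i %% 3 == 0) v[sample(n, 1)] <- runif(1, 2000, 6000)
    if (i %% 5 == 0) v[sample(n, 1)] <- runif(1, 1500, 2100)
    cutoff <- sample(c(1000, 2000, 3000), 1)
    mult <- sample(c(1, 2, 3), 1)
    expect_identical(clean_peak_velocity(v, cutoff, mult)$keep,
                     brute(v, cutoff, mult))
  }
})

test_that("hand theta wraps circularly and matches a brute-force minimizer", {
  # hand at 179 deg, target at -179 deg, no rotation: circular difference -2
  tr <- line_trajectory(angle_deg = 179, v = 400, t_max = 0.4)
  expect_equal(hand_theta(tr, -179, rotation_deg = 0), -2, tolerance = 1e-9)
  # brute force: minimize |hand - target + 360 k| over k
  brute_wrap <- function(hand, target) {
    cand <- hand - target + 360 * (-6:6)
    cand[which.min(abs(cand))]
  }
  set.seed(23)
  for (i in 1:300) {
    hand <- runif(1, -720, 720); target <- runif(1, -720, 720)
    tr <- line_trajectory(angle_deg = hand, v = 400, t_max = 0.4)
    got <- hand_theta(tr, target, rotation_deg = 0)
    want <- brute_wrap(hand, target)
    if (abs(abs(want) - 180) < 1e-6) next   # tie at the branch cut
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("hand theta is invariant under joint rotation of path and target", {
  set.seed(29)
  for (i in 1:50) {
    ang <- runif(1, 0, 360)
    tr <- line_trajectory(angle_deg = ang, v = 500, t_max = 0.3)
    target <- ang + runif(1, -90, 90)
    th0 <- hand_theta(tr, target, rotation_deg = 45)
    by <- runif(1, -180, 180)
    th1 <- hand_theta(rotate_traj(tr, by), target + by, rotation_deg = 45)
    expect_equal(th1, th0, tolerance = 1e-6)
  }
})

test_that("hand theta flags degenerate movements and uses ring crossing", {
  still <- structure(list(t = c(0, 0.1, 0.2, 0.3), x = rep(0, 4), y = rep(0, 4),
                          cue_time = 0), class = "trajectory")
  expect_true(is.na(hand_theta(still, 0)))
  # curved path: ring crossing differs from the last sample
  t <- seq(0, 1, by = 0.004)
  tr <- structure(list(t = t, x = 120 * t, y = 40 * t^2, cue_time = 0),
                  class = "trajectory")
  th_ring <- hand_theta(tr, 0, rotation_deg = 0, ring_radius_mm = 80)
  th_last <- hand_theta(tr, 0, rotation_deg = 0, endpoint = "last")
  expect_lt(th_ring, th_last)   # CCW-curving path: later endpoint, larger angle
  expect_gt(th_ring, 0)
})

test_that("stage summaries average exactly the first and last 8 trials", {
  tab <- tibble::tibble(
    participant = "S01", condition = "adaptation",
    trial_in_condition = 1:32,
    val = c(0:7, rep(45, 16), rep(45, 8)))
  ss <- stage_summary(tab, "val")
  expect_equal(ss$mean[ss$stage == "early"], 3.5)
  expect_equal(ss$mean[ss$stage == "late"], 45)
  # constant measure: both stages equal
  tab$val <- 45
  ss2 <- stage_summary(tab, "val")
  expect_true(all(ss2$mean == 45))
})

test_that("stage summaries match brute-force grouping on random tables", {
  set.seed(37)
  for (i in 1:30) {
    tab <- expand.grid(participant = c("A", "B"),
                       condition = c("adaptation", "retention"),
                       trial_in_condition = 1:24,
                       stringsAsFactors = FALSE)
    tab$val <- rnorm(nrow(tab))
    tab$val[sample(nrow(tab), 10)] <- NA
    tab <- tibble::as_tibble(tab[sample(nrow(tab)), ])
    ss <- stage_summary(tab, "val")
    for (r in seq_len(nrow(ss))) {
      d <- tab[tab$participant == ss$participant[r] &
                 tab$condition == ss$condition[r], ]
      d <- d[order(d$trial_in_condition), ]
      idx <- if (ss$stage[r] == "early") 1:8 else 17:24
      expect_equal(ss$mean[r], mean(d$val[idx], na.rm = TRUE))
      expect_equal(ss$n_used[r], sum(!is.na(d$val[idx])))
    }
  }
})

test_that("short conditions warn and assign overlap to early", {
  tab <- tibble::tibble(participant = "S01", condition = "washout",
                        trial_in_condition = 1:10, val = 1:10)
  expect_warning(ss <- stage_summary(tab, "val"), "overlap")
  expect_equal(ss$mean[ss$stage == "early"], mean(1:8))
  # trials 7-10 would be late, but 7 and 8 belong to early
  expect_equal(ss$mean[ss$stage == "late"], mean(9:10))
})

test_that("zero-noise cohort kinematics reproduce the learner exactly", {
  cfg <- tiny_zero_cfg(seed = 4)
  co <- simulate_cohort(cfg, what = "behavior")
  tt <- build_trial_table(co)$trial_table
  merged <- merge(tt, co$trials,
                  by = c("participant", "trial_index", "condition",
                         "trial_in_condition", "cycle_index", "target_deg"))
  expect_equal(merged$hand_theta, merged$intended_deg, tolerance = 1e-8)
  # early retention mean equals the learner's terminal adaptation state
  ss <- stage_summary(tt[tt$condition %in% c("adaptation", "retention"), ],
                      "hand_theta")
  for (pid in unique(ss$participant)) {
    term <- co$trials$intended_deg[co$trials$participant == pid &
                                     co$trials$condition == "retention"][1]
    er <- ss$mean[ss$participant == pid & ss$condition == "retention" &
                    ss$stage == "early"]
    expect_equal(er, term, tolerance = 1e-8)
  }
})
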