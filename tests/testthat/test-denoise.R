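# helper: bold_ts at an arbitrary pipeline stage
make_ts <- function(data, tr = 3, stage = "raw", frame_status = NULL)
  bold_timeseries(data, tr = tr, frame_status = frame_status, stage = stage)

test_that("framewise displacement follows the closed form", {
  m <- matrix(0, 10, 6)
  expect_equal(compute_fd(m), rep(0, 10))          # no motion

  m2 <- m; m2[5:10, 1] <- 0.1                      # 0.1 mm x-step at frame 5
  fd <- compute_fd(m2)
  expect_equal(fd[5], 0.1)
  expect_equal(fd[-5], rep(0, 9))

  m3 <- m; m3[5:10, 4] <- 0.002                    # 0.002 rad rotation step
  expect_equal(compute_fd(m3, head_radius = 50)[5], 0.002 * 50)

  # combined translations and rotations sum
  m4 <- m; m4[5:10, 1] <- 0.05; m4[5:10, 5] <- 0.001
  expect_equal(compute_fd(m4)[5], 0.05 + 50 * 0.001)

  expect_equal(compute_fd(m)[1], 0)                # FD(1) = 0 by convention
  expect_error(compute_fd(m[, 1:5]), "format error")
  expect_error(compute_fd(m[1, , drop = FALSE]), ">= 2 frames")
})

test_that("nuisance design has the Friston-24 structure", {
  set.seed(1)
  ts <- make_ts(matrix(rnorm(50 * 8), 50))
  motion <- matrix(rnorm(50 * 6, sd = 0.1), 50)
  tissue <- matrix(rnorm(50 * 2), 50,
                   dimnames = list(NULL, c("wm", "csf")))
  x <- build_nuisance(ts, motion, tissue)
  # 3 tissue signals (gs, wm, csf) x 2 + 24 motion-derived columns
  expect_equal(ncol(x), 30)
  expect_equal(sum(grepl("^(d\\.)?mot", colnames(x))), 24)

  # zero motion: the 24 degenerate columns are dropped with a warning
  expect_warning(x0 <- build_nuisance(ts, motion * 0, tissue),
                 "degenerate")
  expect_equal(ncol(x0), 6)

  # first difference of a linear ramp is constant past the padded frame
  ramp <- motion; ramp[, 2] <- seq(0, 1, length.out = 50)
  xr <- build_nuisance(ts, ramp, tissue)
  dcol <- xr[, "d.mot2"]
  expect_lt(max(abs(diff(dcol[-1]))), 1e-12)

  expect_error(build_nuisance(ts, motion[1:10, ], tissue), "mismatch")
})

test_that("demean/detrend removes exactly the linear component", {
  t_idx <- 1:100
  ramp <- make_ts(cbind(2 + 0.5 * t_idx, -1 - 0.1 * t_idx))
  out <- demean_detrend(ramp)
  expect_equal(max(abs(out$data)), 0, tolerance = 1e-10)

  sine <- sin(2 * pi * t_idx / 25)
  mixed <- make_ts(cbind(sine, 3 + 0.2 * t_idx + sine))
  out2 <- demean_detrend(mixed)
  # zero-mean sinusoid with incomplete cycles has a tiny LS line; compare
  # against an explicit least-squares line-removal oracle
  X <- cbind(1, t_idx)
  oracle <- sine - X %*% solve(crossprod(X), crossprod(X, sine))
  expect_lt(max(abs(out2$data[, 1] - oracle)), 1e-8)
  expect_lt(max(abs(out2$data[, 2] - oracle)), 1e-8)
  expect_lt(max(abs(colMeans(out2$data))), 1e-10)

  expect_error(demean_detrend(make_ts(matrix(1:4, 2))), ">= 3 frames")
})

test_that("nuisance regression matches the normal equations and is orthogonal", {
  set.seed(42)
  n <- 20
  nuis <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  beta_true <- c(2, -1, 0.5)
  y_exact <- nuis %*% beta_true
  ts <- make_ts(cbind(y_exact, rnorm(n)), stage = "detrended")
  out <- regress_nuisance(ts, nuis)
  expect_equal(max(abs(out$data[, 1])), 0, tolerance = 1e-10)

  # coefficients equal an explicit normal-equations solve
  y <- ts$data[, 2]
  X <- cbind(1, nuis)
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  resid_oracle <- y - X %*% beta_oracle
  expect_equal(out$data[, 2], as.vector(resid_oracle), tolerance = 1e-10)

  # residuals orthogonal to every regressor
  for (j in 1:3)
    expect_lt(abs(cor(out$data[, 2], nuis[, j])), 1e-10)

  # censored frames excluded from the fit but residualized
  mask <- rep(FALSE, n); mask[3] <- TRUE
  ts2 <- make_ts(cbind(rnorm(n)), stage = "detrended")
  out2 <- regress_nuisance(ts2, nuis, censor_mask = mask)
  clean <- !mask
  Xc <- X[clean, ]
  bc <- solve(crossprod(Xc), crossprod(Xc, ts2$data[clean, 1]))
  expect_equal(out2$data[, 1], as.vector(ts2$data[, 1] - X %*% bc),
               tolerance = 1e-10)

  # duplicated regressor -> rank-deficiency error naming the column
  dup <- cbind(nuis, a2 = nuis[, "a"])
  expect_error(regress_nuisance(make_ts(cbind(rnorm(n)),
                                        stage = "detrended"), dup),
               "rank-deficient.*a2")
})

test_that("scrubbing censors the right frames and interpolates linearly", {
  fd <- c(0, 0.1, 0.4, 0.1)
  ts <- make_ts(cbind(c(1, 2, 99, 4)), stage = "regressed")
  out <- censor_and_interpolate(ts, fd, threshold = 0.3)
  expect_equal(out$frame_status, c("clean", "clean", "interpolated", "clean"))
  expect_equal(sum(out$frame_status == "clean"), 3)
  # linear signal: interpolated interior value lies on the line
  expect_equal(out$data[3, 1], 3)

  # all FD below threshold: untouched
  ts2 <- make_ts(cbind(1:4), stage = "regressed")
  out2 <- censor_and_interpolate(ts2, c(0, 0.1, 0.2, 0.1))
  expect_equal(out2$frame_status, rep("clean", 4))
  expect_equal(out2$data, ts2$data)

  expect_error(censor_and_interpolate(ts2, rep(1, 4)), "all frames")
})

test_that("bandpass filter meets its passband and stopband bounds", {
  tr <- 3
  t_sec <- (0:1199) * tr
  amp_of <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t_sec)
    ts <- make_ts(cbind(x), tr = tr, stage = "scrubbed")
    y <- bandpass(ts)$data[, 1]
    mid <- 300:900  # avoid edge transients
    X <- cbind(sin(2 * pi * f_hz * t_sec[mid]),
               cos(2 * pi * f_hz * t_sec[mid]))
    sqrt(sum(solve(crossprod(X), crossprod(X, y[mid]))^2))
  }
  expect_gte(amp_of(0.04), 0.9)    # passband
  expect_lte(amp_of(0.15), 0.1)    # above the band
  expect_lte(amp_of(0.0045), 0.1)  # one octave below the band

  # constant signal: DC removed
  ts_const <- make_ts(cbind(rep(5, 200)), tr = tr, stage = "scrubbed")
  expect_lt(max(abs(bandpass(ts_const)$data)), 1e-6)

  # infeasible band for the sampling rate
  ts <- make_ts(cbind(rnorm(100)), tr = tr, stage = "scrubbed")
  expect_error(bandpass(ts, 0.009, 0.2), "infeasible")
})

test_that("interpolated-frame removal conserves frames and order", {
  status <- rep("clean", 140)
  status[sample(2:139, 30)] <- "interpolated"
  ts <- make_ts(matrix(seq_len(140 * 2), 140), stage = "filtered",
                frame_status = status)
  out <- drop_interpolated(ts)
  expect_equal(nrow(out$data), 110)
  expect_equal(nrow(out$data) + 30, 140)  # clean + censored partition
  # order preserved: values still increasing down each column
  expect_true(all(diff(out$data[, 1]) > 0))

  ts2 <- make_ts(matrix(rnorm(20), 10), stage = "filtered")
  out2 <- drop_interpolated(ts2)
  expect_equal(out2$data, ts2$data, ignore_attr = TRUE)
})

test_that("QC applies the 100-frame rule with an inclusive boundary", {
  mk <- function(n) make_ts(matrix(rnorm(n * 3), n), stage = "trimmed")
  expect_equal(qc_and_select(mk(99))$verdict, "exclude")
  r140 <- qc_and_select(mk(140))
  expect_equal(r140$verdict, "pass")
  expect_equal(nrow(r140$ts$data), 100)
  r100 <- qc_and_select(mk(100))
  expect_equal(r100$verdict, "pass")
  expect_equal(nrow(r100$ts$data), 100)

  # the first 100 clean frames are the earliest ones
  ts <- make_ts(matrix(1:150, 150, 1), stage = "trimmed")
  expect_equal(qc_and_select(ts)$ts$data[, 1], 1:100)
})

test_that("pipeline stages cannot run out of order", {
  ts <- make_ts(matrix(rnorm(300), 100))
  expect_error(bandpass(ts), "pipeline order")
  expect_error(regress_nuisance(ts, cbind(rnorm(100))), "pipeline order")
  expect_error(drop_interpolated(ts), "pipeline order")
  detr <- demean_detrend(ts)
  expect_error(demean_detrend(detr), "pipeline order")
})

test_that("lowering the FD threshold never increases the clean-frame count", {
  set.seed(8)
  fd <- c(0, abs(rnorm(99, 0.2, 0.15)))
  ts <- make_ts(matrix(rnorm(100 * 2), 100), stage = "regressed")
  counts <- sapply(c(0.5, 0.3, 0.2, 0.1), function(thr)
    sum(censor_and_interpolate(ts, fd, thr)$frame_status == "clean"))
  expect_true(all(diff(counts) <= 0))
})

test_that("frame loss increases with dementia severity in synthetic cohorts", {
  p <- default_partition(20)
  eff <- effect_spec()
  coh <- generate_cohort(cohort_config(n = 80, seed = 77))
  pct_loss <- sapply(seq_len(nrow(coh)), function(i) {
    subj <- coh[i, ]
    cv <- build_generating_covariance(subj, p, eff)
    sim <- generate_subject_timeseries(subj, cv, n_frames = 140,
                                       effects = eff,
                                       seed = subj$subject_seed)
    mean(compute_fd(sim$motion) > 0.3) * 100
  })
  dat <- cbind(coh, pct_loss = pct_loss)
  m <- fit_ols(dat, "pct_loss", "cdr", "age")
  row <- model_term(m, "cdr")
  expect_gt(row$beta, 0)
  expect_lt(row$p, 0.05)
})
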