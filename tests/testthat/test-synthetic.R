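test_that("cohort generation rejects bad configurations and is deterministic", {
  expect_error(cohort_config(n = 0), "size must be >= 1")
  expect_error(cohort_config(n = 10, age_sd = -1), "configuration error")
  expect_error(cohort_config(n = 10, cdr_probs = c(1, 1)),
               "CDR distribution")

  a <- generate_cohort(cohort_config(n = 40, seed = 11))
  b <- generate_cohort(cohort_config(n = 40, seed = 11))
  expect_identical(a, b)
  d <- generate_cohort(cohort_config(n = 40, seed = 12))
  expect_false(identical(a$age, d$age))
})

test_that("growing the cohort does not reshuffle earlier subjects", {
  small <- generate_cohort(cohort_config(n = 15, seed = 3))
  large <- generate_cohort(cohort_config(n = 40, seed = 3))
  expect_identical(small, large[1:15, ])
})

test_that("cohort covariates match the configured distributions", {
  coh <- generate_cohort(cohort_config(n = 10000, seed = 99))
  # law of large numbers against the configured mean age
  expect_lt(abs(mean(coh$age) - 74.70), 0.3)
  expect_true(all(coh$age >= 55 & coh$age <= 96))
  expect_true(all(coh$cdr %in% c(0, 0.5, 1, 2)))
  expect_true(all(coh$education > 0))
  # CDR frequencies within multinomial sampling error of the configuration
  freq <- table(factor(coh$cdr, levels = c(0, 0.5, 1, 2))) / nrow(coh)
  expect_lt(max(abs(freq - c(0.5424, 0.3661, 0.0732, 0.0183))), 0.02)
})

test_that("generating covariance responds to effects as injected", {
  p <- default_partition(30)
  eff0 <- effect_spec(age_slope_within_assoc = 0, cdr_slope_between = 0,
                      cdr_slope_within = 0)
  s1 <- list(age = 60, cdr = 0)
  s2 <- list(age = 90, cdr = 0)
  expect_equal(build_generating_covariance(s1, p, eff0),
               build_generating_covariance(s2, p, eff0))

  # positive CDR slope raises every between-system correlation
  eff <- effect_spec()
  sys <- p$nodes$system
  between <- outer(sys, sys, "!=") & upper.tri(matrix(0, 30, 30))
  c0 <- build_generating_covariance(list(age = 75, cdr = 0), p, eff)
  c1 <- build_generating_covariance(list(age = 75, cdr = 1), p, eff)
  expect_true(all(c1[between] > c0[between]))

  # matrices are valid correlations, PSD up to numerical tolerance
  expect_equal(diag(c1), rep(1, 30), ignore_attr = TRUE)
  expect_gt(min(eigen(c1, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("effect spec validates modularity and rates", {
  expect_error(effect_spec(baseline_within_z = 0.1,
                           baseline_between_z = 0.2),
               "within-z > between-z")
  expect_error(effect_spec(spike_rate_base = 1.2), "spike rates")
  null_eff <- null_effect_spec()
  expect_equal(null_eff$cdr_slope_between, 0)
  expect_equal(null_eff$spike_rate_base, 0)
})

test_that("expected segregation matches closed forms and the oracle", {
  # 2 systems x 2 nodes: within z 0.8 (2 pairs), between z 0.2 (4 pairs)
  p <- toy_partition_2x2()
  r <- tanh(toy_block_matrix(p, 0.8, 0.2))
  r[is.na(r)] <- 0; diag(r) <- 1
  expect_equal(expected_segregation(r, p), (0.8 - 0.2) / 0.8)

  # block-diagonal: between = 0 -> maximal segregation of 1
  rd <- tanh(toy_block_matrix(p, 0.5, 0))
  rd[is.na(rd)] <- 0; diag(rd) <- 1
  expect_equal(expected_segregation(rd, p), 1)

  # uniform correlation: within mean = between mean -> 0
  ru <- matrix(0.3, 4, 4, dimnames = list(p$nodes$node_id, p$nodes$node_id))
  diag(ru) <- 1
  expect_equal(expected_segregation(ru, p), 0)

  # generating covariance segregation equals brute-force enumeration
  eff <- effect_spec()
  p2 <- default_partition(30)
  cv <- build_generating_covariance(list(age = 80, cdr = 0.5), p2, eff)
  z <- atanh(pmin(pmax(cv, -1 + 1e-7), 1 - 1e-7))
  z[z < 0] <- 0
  diag(z) <- NA
  expect_equal(expected_segregation(cv, p2),
               oracle_global_segregation(z, p2))
})

test_that("subject time series are reproducible and respect spike settings", {
  p <- default_partition(20)
  eff <- effect_spec()
  subj <- list(age = 75, cdr = 0.5)
  cv <- build_generating_covariance(subj, p, eff)
  a <- generate_subject_timeseries(subj, cv, n_frames = 60, seed = 5,
                                   effects = eff)
  b <- generate_subject_timeseries(subj, cv, n_frames = 60, seed = 5,
                                   effects = eff)
  expect_identical(a, b)
  expect_error(generate_subject_timeseries(subj, cv, n_frames = 0,
                                           seed = 5, effects = eff),
               "n_frames")

  # no spikes and no jitter: motion trace constant, FD identically zero
  still <- effect_spec(spike_rate_base = 0, spike_rate_cdr = 0,
                       motion_jitter_sd = 0)
  s <- generate_subject_timeseries(subj, cv, n_frames = 60, seed = 5,
                                   effects = still)
  expect_true(all(s$motion == 0))
  expect_true(all(compute_fd(s$motion) == 0))
})

test_that("spike contamination increases with CDR", {
  p <- default_partition(20)
  eff <- effect_spec()
  frac <- sapply(c(0, 2), function(cdr) {
    subj <- list(age = 75, cdr = cdr)
    cv <- build_generating_covariance(subj, p, eff)
    mean(sapply(1:30, function(s)
      length(generate_subject_timeseries(subj, cv, n_frames = 140,
                                         seed = s, effects = eff
      )$spike_frames) / 140))
  })
  expect_gt(frac[2], frac[1])
  expect_equal(frac[1], eff$spike_rate_base, tolerance = 0.25)
})

test_that("sample correlations converge to the target at the 1/sqrt(frames) rate", {
  p <- default_partition(30)
  eff <- effect_spec(noise_sd = 0)
  subj <- list(age = 70, cdr = 0)
  cv <- build_generating_covariance(subj, p, eff)
  dev_at <- function(nf, seed) {
    sim <- generate_subject_timeseries(
      subj, cv, n_frames = nf, seed = seed,
      effects = effect_spec(noise_sd = 0, spike_rate_base = 0,
                            spike_rate_cdr = 0))
    d <- abs(cor(sim$ts$data) - cv)
    c(max = max(d), mean = mean(d[upper.tri(d)]))
  }
  d_50k <- dev_at(50000, 1)
  expect_lt(d_50k["max"], 0.02)   # Monte-Carlo convergence check
  d_500 <- dev_at(500, 2)
  # 100x more frames -> ~10x smaller mean deviation (allow wide slack)
  ratio <- d_500["mean"] / d_50k["mean"]
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("with all slopes zero downstream regressions find no effects", {
  p <- default_partition(30)
  eff <- null_effect_spec()
  cover_age <- cover_cdr <- logical(100)
  for (r in 1:100) {
    coh <- generate_cohort(cohort_config(n = 60, seed = 500 + r))
    seg <- sapply(seq_len(nrow(coh)), function(i) {
      net <- simulate_connectivity(coh[i, ], p, eff, n_frames = 100,
                                   seed = coh$subject_seed[i])
      system_segregation(net, p)$global_segregation
    })
    dat <- cbind(coh, seg = seg)
    m <- fit_ols(dat, "seg", c("age", "cdr"), c("gender", "education"))
    age_row <- model_term(m, "age")
    cdr_row <- model_term(m, "cdr")
    cover_age[r] <- age_row$ci_lo <= 0 && 0 <= age_row$ci_hi
    cover_cdr[r] <- cdr_row$ci_lo <= 0 && 0 <= cdr_row$ci_hi
  }
  expect_gte(mean(cover_age), 0.9)
  expect_gte(mean(cover_cdr), 0.9)
})

test_that("default nonzero slopes are recovered in sign in >= 95% of replicates", {
  study <- cached_dissociation_study()
  expect_equal(nrow(study), 50)
  expect_gte(mean(study$age_assoc_beta < 0), 0.95)
  expect_gte(mean(study$cdr_between_beta > 0), 0.95)
})

test_that("ground truth reports the generating covariance and slopes", {
  p <- default_partition(20)
  eff <- effect_spec()
  gt <- subject_ground_truth(list(age = 80, cdr = 1), p, eff)
  expect_equal(dim(gt$covariance), c(20, 20))
  expect_equal(gt$slopes$cdr_slope_between, eff$cdr_slope_between)
  expect_lt(gt$expected_segregation, 1)
  expect_gt(gt$expected_segregation, 0)
})
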