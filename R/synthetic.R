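#' Cohort configuration for the synthetic generator
#'
#' Defaults emulate a memory-clinic aging cohort: ages truncated-normal
#' with mean 74.70 and SD 8.11 on 55-96 years, Clinical Dementia Rating
#' (CDR) drawn from \{0, 0.5, 1, 2\} with probabilities matching the
#' observed group sizes (roughly 54\% / 37\% / 7\% / 2\%), 53\% female,
#' education 16.5 (SD 2.45) years, and optional pulse / respiration
#' channels.
#'
#' @param n cohort size (>= 1).
#' @param age_mean,age_sd,age_range age distribution (years), truncated to
#'   `age_range`.
#' @param cdr_levels,cdr_probs admissible CDR scores and their sampling
#'   probabilities.
#' @param female_prob probability of gender `"F"`.
#' @param education_mean,education_sd,education_min education (years).
#' @param pulse_mean,pulse_sd,respiration_mean,respiration_sd vital signs;
#'   set a mean to `NA` to omit the column.
#' @param seed master seed; one master seed spawns an independent stream
#'   per subject, so growing the cohort never reshuffles earlier subjects.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n,
                          age_mean = 74.70, age_sd = 8.11,
                          age_range = c(55, 96),
                          cdr_levels = c(0, 0.5, 1, 2),
                          cdr_probs = c(0.5424, 0.3661, 0.0732, 0.0183),
                          female_prob = 0.5324,
                          education_mean = 16.5, education_sd = 2.45,
                          education_min = 6,
                          pulse_mean = 64.39, pulse_sd = 10.31,
                          respiration_mean = 16.09, respiration_sd = 2.36,
                          seed = 1L) {
  if (length(n) != 1 || is.na(n) || n < 1)
    stop("configuration error: cohort size must be >= 1")
  if (length(cdr_levels) != length(cdr_probs) || any(cdr_probs < 0) ||
      sum(cdr_probs) <= 0)
    stop("configuration error: invalid CDR distribution")
  if (age_sd <= 0 || education_sd <= 0 || diff(age_range) <= 0)
    stop("configuration error: invalid covariate distribution parameters")
  structure(as.list(environment()), class = "cohort_config")
}

# truncated normal by rejection; range is wide enough that this terminates
# quickly for all sane configs
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic cohort covariate table
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per subject: `subject_id`, `age`, `cdr`,
#'   `gender`, `education`, `pulse`, `respiration`, `mean_fd_post` (filled
#'   after denoising, `NA` here) and `subject_seed` (the per-subject
#'   random stream seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- as.integer(config$n)
  withr_seed <- config$seed
  set.seed(withr_seed)
  subject_seed <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)

  draw_one <- function(i) {
    set.seed(subject_seed[i])
    age <- .rtruncnorm(1, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2])
    cdr <- sample(config$cdr_levels, 1,
                  prob = config$cdr_probs / sum(config$cdr_probs))
    gender <- if (stats::runif(1) < config$female_prob) "F" else "M"
    edu <- round(.rtruncnorm(1, config$education_mean, config$education_sd,
                             config$education_min, Inf))
    pulse <- if (is.na(config$pulse_mean)) NA_real_ else
      stats::rnorm(1, config$pulse_mean, config$pulse_sd)
    resp <- if (is.na(config$respiration_mean)) NA_real_ else
      stats::rnorm(1, config$respiration_mean, config$respiration_sd)
    data.frame(age = age, cdr = cdr, gender = gender, education = edu,
               pulse = pulse, respiration = resp,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(seq_len(n), draw_one))
  data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
             tab,
             mean_fd_post = NA_real_,
             subject_seed = subject_seed,
             stringsAsFactors = FALSE)
}

#' Effect specification for the generating covariance
#'
#' Effects are injected linearly on the Fisher-z scale, the natural scale
#' of the downstream linear models. The block-structured generating
#' correlation of a subject is built from baseline within- and
#' between-system z values modulated by the subject's age and CDR:
#' * age lowers within-system z of *association* systems only
#'   (`age_slope_within_assoc` per year, centred at `age_center`);
#' * CDR lowers within-system z of systems of both types
#'   (`cdr_slope_within` per CDR unit) and raises between-system z
#'   (`cdr_slope_between` per CDR unit).
#'
#' Motion-spike contamination increases with CDR: per-frame spike
#' probability is `spike_rate_base + spike_rate_cdr * cdr`.
#'
#' Default magnitudes are chosen for detectability at cohorts of a few
#' hundred subjects (the source phenomena are reported only as directions
#' and standardized effects, not z-scale slopes).
#'
#' @param baseline_within_z within-system Fisher z; scalar or named per
#'   system.
#' @param baseline_between_z between-system Fisher z (scalar).
#' @param age_slope_within_assoc change in within-system z of association
#'   systems per year of age (negative).
#' @param cdr_slope_between change in between-system z per CDR unit
#'   (positive).
#' @param cdr_slope_within change in within-system z per CDR unit
#'   (negative).
#' @param noise_sd SD of i.i.d. sensor noise added to each node signal
#'   (signal units; node signals have unit variance before noise).
#' @param spike_rate_base,spike_rate_cdr motion spike probability per frame
#'   at CDR 0 and its increase per CDR unit.
#' @param motion_jitter_sd SD (mm) of the per-frame baseline translation
#'   jitter (rotation jitter is `motion_jitter_sd / 100` rad); the default
#'   0.03 mm yields mean framewise displacement near 0.15 mm, typical of
#'   an older cohort, while staying below the scrubbing threshold. Set to
#'   0 for a perfectly still subject (FD identically 0 when spike rates
#'   are also 0).
#' @param age_center age (years) at which within-association z equals its
#'   baseline.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(baseline_within_z = 0.6,
                        baseline_between_z = 0.15,
                        age_slope_within_assoc = -0.004,
                        cdr_slope_between = 0.04,
                        cdr_slope_within = -0.03,
                        noise_sd = 0.5,
                        spike_rate_base = 0.03,
                        spike_rate_cdr = 0.08,
                        motion_jitter_sd = 0.03,
                        age_center = 74.70) {
  if (any(baseline_within_z <= baseline_between_z))
    stop("modular structure requires all baseline within-z > between-z")
  if (spike_rate_base < 0 || spike_rate_base > 1 || spike_rate_cdr < 0)
    stop("spike rates must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (motion_jitter_sd < 0) stop("motion_jitter_sd must be >= 0")
  structure(as.list(environment()), class = "effect_spec")
}

#' Null effect specification
#'
#' All age/CDR slopes and spike rates set to zero; used for type-I-error
#' calibration of the inferential layer.
#'
#' @param ... overrides passed to [effect_spec()].
#' @export
null_effect_spec <- function(...) {
  args <- list(age_slope_within_assoc = 0, cdr_slope_between = 0,
               cdr_slope_within = 0, spike_rate_base = 0,
               spike_rate_cdr = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(effect_spec, args)
}

# internal: per-system within-z and scalar between-z for one subject
.subject_block_z <- function(subject, partition, effects) {
  types <- .assigned_system_types(partition)
  systems <- names(types)
  bw <- effects$baseline_within_z
  if (is.null(names(bw))) {
    bw <- stats::setNames(rep(bw[1], length(systems)), systems)
  } else {
    missing <- setdiff(systems, names(bw))
    if (length(missing)) stop("baseline_within_z missing systems: ",
                              paste(missing, collapse = ", "))
    bw <- bw[systems]
  }
  dage <- subject$age - effects$age_center
  wz <- bw + effects$cdr_slope_within * subject$cdr +
    ifelse(types == "association",
           effects$age_slope_within_assoc * dage, 0)
  bz <- effects$baseline_between_z +
    effects$cdr_slope_between * subject$cdr
  list(within_z = wz, between_z = bz)
}

#' Build a subject's generating covariance
#'
#' Block-constant correlation matrix on the nodes of `partition`:
#' within-system blocks at the subject's modulated within-z, between-system
#' blocks at the modulated between-z, converted z to r by `tanh`. If effect
#' modulation makes the matrix indefinite it is repaired by clipping
#' negative eigenvalues at zero and renormalizing to a unit diagonal.
#'
#' @param subject one-row data.frame (or list) with at least `age` and
#'   `cdr`.
#' @param partition a [system_partition()]; unassigned-type systems receive
#'   the between-system correlation with every other node.
#' @param effects an [effect_spec()].
#' @return node x node correlation matrix with node ids as dimnames.
#' @export
build_generating_covariance <- function(subject, partition, effects) {
  blocks <- .subject_block_z(subject, partition, effects)
  sys <- .partition_systems(partition)
  n <- length(sys)
  zmat <- matrix(blocks$between_z, n, n)
  for (s in names(blocks$within_z)) {
    idx <- which(!is.na(sys) & sys == s)
    zmat[idx, idx] <- blocks$within_z[[s]]
  }
  r <- tanh(zmat)
  if (any(abs(r) >= 1)) {  # tanh keeps |r| < 1; guard kept for safety
    warning("generating correlations clipped to (-1, 1)")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  diag(r) <- 1
  r <- .psd_repair(r)
  dimnames(r) <- list(partition$nodes$node_id, partition$nodes$node_id)
  r
}

# eigenvalue clipping at 0 + renormalization to unit diagonal
.psd_repair <- function(r, tol = 1e-10) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= -tol) return(r)
  v <- pmax(e$values, 0)
  m <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  (m + t(m)) / 2
}

#' Exact segregation of a generating correlation matrix
#'
#' Noise-free oracle: applies the Fisher z-transform and negative zeroing
#' to the off-diagonal generating correlations, then computes the pooled
#' segregation index (mean within-system z minus mean between-system z,
#' over mean within-system z) by exhaustive enumeration of node pairs.
#'
#' @param covariance node x node correlation matrix.
#' @param partition a [system_partition()].
#' @return scalar segregation value (<= 1; 1 when every between-system
#'   correlation is zero).
#' @export
expected_segregation <- function(covariance, partition) {
  sys <- .partition_systems(partition,
                            node_ids = rownames(covariance) %||%
                              partition$nodes$node_id)
  n <- nrow(covariance)
  w <- c(); b <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.na(sys[i]) || is.na(sys[j])) next
      z <- atanh(min(max(covariance[i, j], -1 + 1e-7), 1 - 1e-7))
      if (z < 0) z <- 0
      if (sys[i] == sys[j]) w <- c(w, z) else b <- c(b, z)
    }
  }
  mw <- mean(w)
  if (!is.finite(mw) || mw == 0)
    stop("undefined segregation: mean within-system value is 0")
  (mw - mean(b)) / mw
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground truth for one subject
#'
#' @inheritParams build_generating_covariance
#' @return list: `covariance` (generating correlation matrix),
#'   `expected_segregation` (noise-free segregation of that matrix) and
#'   `slopes` (the injected effect slopes).
#' @export
subject_ground_truth <- function(subject, partition, effects) {
  covariance <- build_generating_covariance(subject, partition, effects)
  list(covariance = covariance,
       expected_segregation = expected_segregation(covariance, partition),
       slopes = effects[c("age_slope_within_assoc", "cdr_slope_between",
                          "cdr_slope_within")])
}

#' Simulate one subject's BOLD time series and motion trace
#'
#' Node signals are zero-mean multivariate normal draws with the subject's
#' generating covariance plus i.i.d. sensor noise (`effects$noise_sd`).
#' Motion is a small Gaussian jitter of the six rigid-body parameters
#' (framewise displacement around 0.15 mm) with spike contamination:
#' at Bernoulli(spike_rate_base + spike_rate_cdr * cdr) frames a 1 mm
#' x-translation excursion is injected (framewise displacement far above
#' the 0.3 mm scrubbing threshold) together with a global additive
#' artifact on all nodes at that frame. White-matter and ventricle
#' surrogate channels (unit-variance noise carrying half the global
#' artifact) are returned for nuisance regression.
#'
#' @param subject one-row data.frame with `age`, `cdr`.
#' @param covariance generating correlation matrix
#'   (from [build_generating_covariance()]).
#' @param n_frames number of frames (>= 1); 140 matches the shortest
#'   acquisition of the emulated protocol (140-200 frames at TR 3 s).
#' @param tr repetition time, seconds.
#' @param effects an [effect_spec()].
#' @param seed integer seed for this subject's stream.
#' @return list: `ts` (a [bold_timeseries()]), `motion` (frames x 6 matrix:
#'   3 translations mm, 3 rotations rad), `tissue` (frames x 2 surrogate
#'   matrix, columns `wm`, `csf`), `spike_frames` (integer vector).
#' @export
generate_subject_timeseries <- function(subject, covariance,
                                        n_frames = 140, tr = 3,
                                        effects = effect_spec(),
                                        seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed)
  n_nodes <- nrow(covariance)
  ch <- chol(covariance + diag(1e-10, n_nodes))
  y <- matrix(stats::rnorm(n_frames * n_nodes), n_frames) %*% ch
  if (effects$noise_sd > 0)
    y <- y + effects$noise_sd * matrix(stats::rnorm(n_frames * n_nodes),
                                       n_frames)

  # baseline motion jitter: mean FD ~ 0.15 mm at defaults, spikes cross
  # the 0.3 mm scrubbing threshold unambiguously
  js <- effects$motion_jitter_sd
  motion <- cbind(
    matrix(stats::rnorm(n_frames * 3), n_frames) * js,
    matrix(stats::rnorm(n_frames * 3), n_frames) * js / 100)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  rate <- min(max(effects$spike_rate_base +
                    effects$spike_rate_cdr * subject$cdr, 0), 1)
  spike <- which(stats::runif(n_frames) < rate)
  if (length(spike)) {
    motion[spike, "trans_x"] <- motion[spike, "trans_x"] + 1.0
    y[spike, ] <- y[spike, ] + stats::rnorm(length(spike), sd = 4)
  }

  tissue <- cbind(wm = stats::rnorm(n_frames), csf = stats::rnorm(n_frames))
  if (length(spike)) tissue[spike, ] <- tissue[spike, ] + 2

  colnames(y) <- rownames(covariance)
  list(ts = bold_timeseries(y, tr = tr),
       motion = motion,
       tissue = tissue,
       spike_frames = spike)
}

#' Fast path: simulate a subject's connectivity matrix directly
#'
#' Draws `n_frames` multivariate-normal frames from the subject's
#' generating covariance (plus sensor noise), then builds the Fisher-z
#' connectivity matrix with negatives zeroed. Equivalent to the full
#' simulate-denoise-netbuild chain when motion spikes are absent; used by
#' replicate studies where simulating motion artifacts for thousands of
#' subjects would be wasteful.
#'
#' @inheritParams generate_subject_timeseries
#' @param partition a [system_partition()].
#' @return a `connectivity_matrix` (negatives zeroed).
#' @export
simulate_connectivity <- function(subject, partition,
                                  effects = effect_spec(),
                                  n_frames = 100, seed = 1L) {
  covariance <- build_generating_covariance(subject, partition, effects)
  set.seed(seed)
  n_nodes <- nrow(covariance)
  ch <- chol(covariance + diag(1e-10, n_nodes))
  y <- matrix(stats::rnorm(n_frames * n_nodes), n_frames) %*% ch
  if (effects$noise_sd > 0)
    y <- y + effects$noise_sd * matrix(stats::rnorm(n_frames * n_nodes),
                                       n_frames)
  colnames(y) <- rownames(covariance)
  zero_negatives(correlation_matrix(y))
}
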