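#' Replicate study of the age / dementia dissociation
#'
#' Generates `n_reps` independent cohorts from the synthetic generator,
#' computes each subject's connectivity via the direct simulation path
#' ([simulate_connectivity()]; the motion-artifact chain is validated
#' separately and is irrelevant to effect recovery), and for each
#' replicate fits the covariate-controlled regressions of
#' association-system segregation, sensory-motor-system segregation and
#' mean between-system interactions on age and CDR, plus the
#' random-intercept interaction models for system type.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param effects an [effect_spec()] (default: the standard nonzero
#'   slopes).
#' @param partition a [system_partition()].
#' @param n_frames frames used per subject connectivity matrix.
#' @param seed master seed; replicate r uses `seed + r` for its cohort.
#' @param fit_mixed also fit the mixed interaction models (slower).
#' @return data.frame with one row per replicate: focal betas and
#'   p-values (`age_assoc_beta`, `age_assoc_p`, `age_sm_p`,
#'   `cdr_between_beta`, `cdr_between_p`, and if `fit_mixed` the
#'   `age_x_type_p`, `cdr_x_type_p` interaction p-values).
#' @export
replicate_dissociation <- function(n_reps = 50, n_subjects = 300,
                                   effects = effect_spec(),
                                   partition = default_partition(),
                                   n_frames = 100, seed = 1L,
                                   fit_mixed = TRUE) {
  covs <- c("gender", "education")
  one_rep <- function(r) {
    cohort <- generate_cohort(cohort_config(n = n_subjects,
                                            seed = seed + r))
    rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      subj <- cohort[i, ]
      net <- simulate_connectivity(subj, partition, effects,
                                   n_frames = n_frames,
                                   seed = subj$subject_seed)
      seg <- system_segregation(net, partition)
      mi <- mean_interactions(net, partition)
      rows[[i]] <- data.frame(assoc = seg$assoc_segregation,
                              sensorimotor = seg$sensorimotor_segregation,
                              mean_within = unname(mi["mean_within_z"]),
                              mean_between = unname(mi["mean_between_z"]))
    }
    dat <- cbind(cohort, do.call(rbind, rows))
    m_assoc <- fit_ols(dat, "assoc", c("age", "cdr"), covs)
    m_sm <- fit_ols(dat, "sensorimotor", c("age", "cdr"), covs)
    m_btw <- fit_ols(dat, "mean_between", c("age", "cdr"), covs)
    out <- data.frame(
      rep = r,
      age_assoc_beta = model_term(m_assoc, "age")$beta,
      age_assoc_p = model_term(m_assoc, "age")$p,
      age_sm_beta = model_term(m_sm, "age")$beta,
      age_sm_p = model_term(m_sm, "age")$p,
      cdr_between_beta = model_term(m_btw, "cdr")$beta,
      cdr_between_p = model_term(m_btw, "cdr")$p,
      age_assoc_ci_lo = model_term(m_assoc, "age")$ci_lo,
      age_assoc_ci_hi = model_term(m_assoc, "age")$ci_hi,
      cdr_between_ci_lo = model_term(m_btw, "cdr")$ci_lo,
      cdr_between_ci_hi = model_term(m_btw, "cdr")$ci_hi
    )
    if (fit_mixed) {
      long_type <- rbind(
        data.frame(dat[c("subject_id", "age", "cdr", covs)],
                   condition = "association", outcome = dat$assoc),
        data.frame(dat[c("subject_id", "age", "cdr", covs)],
                   condition = "sensory-motor",
                   outcome = dat$sensorimotor))
      m_age_type <- fit_interaction_mixed(long_type, "outcome",
                                          "condition", covariates = covs,
                                          scheme = "age_condition")
      m_cdr_type <- fit_interaction_mixed(long_type, "outcome",
                                          "condition", covariates = covs,
                                          scheme = "cdr_condition")
      int_term <- function(m, prefix) {
        idx <- grepl(paste0("^", prefix, ":condition"), m$terms$term)
        m$terms$p[idx][1]
      }
      out$age_x_type_p <- int_term(m_age_type, "age")
      out$cdr_x_type_p <- int_term(m_cdr_type, "cdr")
    }
    out
  }
  do.call(rbind, lapply(seq_len(n_reps), one_rep))
}

#' Type-I-error calibration of the block permutation test
#'
#' Simulates null cohorts (all effect slopes zero, so CDR has no effect
#' on connectivity), builds each subject's block table through the
#' connectivity simulation path, runs the covariate-controlled
#' Freedman-Lane permutation test of CDR on every block, and returns the
#' per-block p-values of every replicate. Under the null the rejection
#' fraction at level alpha should match alpha.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param n_perm permutations per test.
#' @param partition a [system_partition()].
#' @param n_frames frames per subject connectivity matrix.
#' @param seed master seed.
#' @return data.frame: `rep`, `block`, `p`.
#' @export
permutation_calibration <- function(n_reps = 500, n_subjects = 150,
                                    n_perm = 200,
                                    partition = default_partition(),
                                    n_frames = 100, seed = 1L) {
  effects <- null_effect_spec()
  covs <- c("age", "gender", "education")
  # covariance identical across subjects under the null: factor once
  proto <- list(age = 75, cdr = 0)
  covariance <- build_generating_covariance(proto, partition, effects)
  ch <- chol(covariance + diag(1e-10, nrow(covariance)))
  n_nodes <- nrow(covariance)
  systems <- partition$systems$system[partition$systems$type != "unassigned"]
  lab <- outer(systems, systems, paste, sep = "|")
  block_names <- lab[upper.tri(lab, diag = TRUE)]

  one_rep <- function(r) {
    cohort <- generate_cohort(cohort_config(n = n_subjects,
                                            seed = seed + r))
    bl <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      set.seed(cohort$subject_seed[i])
      y <- matrix(stats::rnorm(n_frames * n_nodes), n_frames) %*% ch
      if (effects$noise_sd > 0)
        y <- y + effects$noise_sd *
          matrix(stats::rnorm(n_frames * n_nodes), n_frames)
      colnames(y) <- rownames(covariance)
      net <- zero_negatives(correlation_matrix(y))
      bm <- block_matrix(net, partition)
      bl[[i]] <- bm[upper.tri(bm, diag = TRUE)]
    }
    blocks <- do.call(rbind, bl)
    colnames(blocks) <- block_names
    res <- block_permutation_test(blocks, cohort, focal = "cdr",
                                  covariates = covs, n_perm = n_perm,
                                  seed = seed + 10000L + r)
    data.frame(rep = r, block = res$table$block, p = res$table$p,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(n_reps), one_rep))
}
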