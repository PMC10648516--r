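#' Pipeline configuration
#'
#' One configuration object drives the full simulate - denoise - netbuild
#' - segregate - analyze chain. All stage parameters are validated before
#' any stage runs, and the configuration round-trips through JSON
#' unchanged.
#'
#' @param n_subjects cohort size.
#' @param seed master seed; simulation and permutation streams are derived
#'   from it independently.
#' @param n_frames frames per simulated acquisition.
#' @param tr repetition time, seconds.
#' @param fd_threshold scrubbing threshold, mm.
#' @param band bandpass edges, Hz.
#' @param min_frames,n_select QC minimum and selected clean-frame count.
#' @param n_nodes node count of the default partition (ignored when
#'   `partition_file` is given).
#' @param partition_file optional path to a partition TSV.
#' @param n_perm permutations for the block tests.
#' @param cohort named list of overrides for [cohort_config()].
#' @param effects named list of overrides for [effect_spec()].
#' @param write_intermediate write per-subject time-series and motion
#'   TSVs (`TRUE` mirrors the on-disk layout; `FALSE` keeps runs light).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 300, seed = 1L,
                            n_frames = 140, tr = 3,
                            fd_threshold = 0.3, band = c(0.009, 0.08),
                            min_frames = 100, n_select = 100,
                            n_nodes = 120, partition_file = NULL,
                            n_perm = 1000,
                            cohort = list(), effects = list(),
                            write_intermediate = TRUE) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
validate_config <- function(config) {
  with(config, {
    if (n_subjects < 1) stop("config error: n_subjects must be >= 1")
    if (n_frames < 1) stop("config error: n_frames must be >= 1")
    if (tr <= 0) stop("config error: tr must be > 0")
    if (fd_threshold <= 0) stop("config error: fd_threshold must be > 0")
    if (!(0 < band[1] && band[1] < band[2] && band[2] < 1 / (2 * tr)))
      stop("config error: infeasible bandpass band")
    if (n_select > n_frames)
      stop("config error: n_select exceeds n_frames")
    if (n_perm < 100) stop("config error: n_perm must be >= 100")
  })
  # constructor errors surface immediately for invalid overrides
  do.call(cohort_config, c(list(n = config$n_subjects,
                                seed = config$seed), config$cohort))
  do.call(effect_spec, config$effects)
  invisible(config)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$band <- as.numeric(raw$band)
  do.call(pipeline_config, raw)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[netseg:%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Orchestrates simulate, denoise, netbuild, segregate and analyze from
#' one configuration. Intermediate artifacts are plain TSV/JSON so every
#' stage is inspectable without the toolkit; a rerun with the same
#' configuration and seed is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @return a `run_report` list: per-stage subject counts, QC table,
#'   segregation summary, model results, block test results, master seed
#'   and package version.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  write_files <- !is.null(out_dir)

  ## --- simulate ------------------------------------------------------
  stage <- "simulate"
  result <- tryCatch({
    partition <- if (!is.null(config$partition_file))
      read_partition(config$partition_file)
    else default_partition(config$n_nodes)
    effects <- do.call(effect_spec, config$effects)
    cohort <- generate_cohort(
      do.call(cohort_config, c(list(n = config$n_subjects,
                                    seed = config$seed), config$cohort)))
    .log_stage(stage, nrow(cohort), " subjects simulated")

    subjects <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      subj <- cohort[i, ]
      covariance <- build_generating_covariance(subj, partition, effects)
      subjects[[i]] <- generate_subject_timeseries(
        subj, covariance, n_frames = config$n_frames, tr = config$tr,
        effects = effects, seed = subj$subject_seed)
    }
    if (write_files) {
      write_partition(partition, file.path(out_dir, "partition.tsv"))
      utils::write.table(cohort, file.path(out_dir, "covariates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (isTRUE(config$write_intermediate)) {
        for (i in seq_len(nrow(cohort))) {
          id <- cohort$subject_id[i]
          utils::write.table(
            subjects[[i]]$ts$data,
            file.path(out_dir, paste0(id, "_timeseries.tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
          utils::write.table(
            subjects[[i]]$motion,
            file.path(out_dir, paste0(id, "_motion.tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
    list(partition = partition, effects = effects, cohort = cohort,
         subjects = subjects)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  partition <- result$partition; effects <- result$effects
  cohort <- result$cohort; subjects <- result$subjects

  ## --- denoise -------------------------------------------------------
  stage <- "denoise"
  qc <- vector("list", nrow(cohort))
  selected <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    res <- tryCatch(
      denoise_subject(subjects[[i]]$ts, subjects[[i]]$motion,
                      tissue_surrogates = subjects[[i]]$tissue,
                      fd_threshold = config$fd_threshold,
                      band = config$band,
                      min_frames = config$min_frames,
                      n_select = config$n_select),
      error = function(e)
        stop("pipeline failed at stage 'denoise', subject ",
             cohort$subject_id[i], ": ", conditionMessage(e),
             call. = FALSE))
    qc[[i]] <- data.frame(subject_id = cohort$subject_id[i],
                          clean_frames = res$clean_frames,
                          pct_loss = res$pct_loss,
                          verdict = res$verdict,
                          mean_fd_pre = res$mean_fd_pre,
                          mean_fd_post = res$mean_fd_post,
                          stringsAsFactors = FALSE)
    selected[[i]] <- res$ts
  }
  qc_report <- do.call(rbind, qc)
  cohort$mean_fd_post <- qc_report$mean_fd_post
  analyzed <- which(qc_report$verdict == "pass")
  .log_stage(stage, length(analyzed), " passed QC, ",
             nrow(cohort) - length(analyzed), " excluded")
  if (!length(analyzed))
    stop("pipeline failed at stage 'denoise': all subjects excluded by QC",
         call. = FALSE)
  if (write_files)
    utils::write.table(qc_report, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- netbuild + segregate ------------------------------------------
  stage <- "segregate"
  seg_rows <- vector("list", length(analyzed))
  block_rows <- vector("list", length(analyzed))
  for (k in seq_along(analyzed)) {
    i <- analyzed[k]
    out <- tryCatch({
      net <- build_network(selected[[i]])
      seg <- system_segregation(net, partition)
      bm <- block_matrix(net, partition)
      mi <- mean_interactions(net, partition)
      list(seg = seg, bm = bm, mi = mi)
    }, error = function(e)
      stop("pipeline failed at stage 'segregate', subject ",
           cohort$subject_id[i], ": ", conditionMessage(e), call. = FALSE))
    seg_rows[[k]] <- data.frame(
      subject_id = cohort$subject_id[i],
      global = out$seg$global_segregation,
      assoc = out$seg$assoc_segregation,
      sensorimotor = out$seg$sensorimotor_segregation,
      mean_within = unname(out$mi["mean_within_z"]),
      mean_between = unname(out$mi["mean_between_z"]),
      stringsAsFactors = FALSE)
    bl <- block_long(out$bm)
    bl$subject_id <- cohort$subject_id[i]
    block_rows[[k]] <- bl
  }
  seg_tab <- do.call(rbind, seg_rows)
  blocks_long <- do.call(rbind, block_rows)
  if (write_files) {
    utils::write.table(seg_tab, file.path(out_dir, "segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(blocks_long, file.path(out_dir, "blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- analyze -------------------------------------------------------
  stage <- "analyze"
  report_models <- tryCatch(
    analyze_cohort(seg_tab, blocks_long, cohort,
                   n_perm = config$n_perm,
                   seed = config$seed + 1L),
    error = function(e)
      stop("pipeline failed at stage 'analyze': ", conditionMessage(e),
           call. = FALSE))
  .log_stage(stage, "models fitted")

  report <- list(
    package_version = as.character(utils::packageVersion("netseg")),
    master_seed = config$seed,
    counts = list(simulated = nrow(cohort),
                  qc_excluded = nrow(cohort) - length(analyzed),
                  analyzed = length(analyzed)),
    qc = qc_report,
    segregation_summary = seg_tab,
    models = report_models$models,
    block_tests = report_models$block_tests,
    dissociation = report_models$dissociation
  )
  class(report) <- "run_report"
  if (write_files) {
    serializable <- report
    serializable$models <- lapply(report_models$models, function(m)
      m[c("terms", "r2", "adj_r2", "marginal_r2", "conditional_r2", "n",
          "formula")])
    jsonlite::write_json(serializable, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE, dataframe = "rows")
  }
  report
}

#' Covariate-controlled analysis of a segregation table
#'
#' The inferential layer run by the pipeline: multiple regression of
#' global, association-system and sensory-motor-system segregation and of
#' the two mean-interaction outcomes on age and CDR (continuous), with
#' gender, post-scrubbing motion and education as covariates;
#' random-intercept mixed models for the age x system-type and
#' CDR x interaction-type contrasts; and the Freedman-Lane block
#' permutation test of CDR across all unique blocks.
#'
#' @param seg_tab per-subject segregation table (from the segregate
#'   stage): columns `subject_id`, `global`, `assoc`, `sensorimotor`,
#'   `mean_within`, `mean_between`.
#' @param blocks_long long block table: `subject_id`, `system_a`,
#'   `system_b`, `mean_z` (`NULL` skips the permutation test).
#' @param covariates_tab cohort covariate table with `subject_id`, `age`,
#'   `cdr`, `gender`, `education`, `mean_fd_post`.
#' @param n_perm,seed permutation parameters.
#' @return list with `models` (named list of `netseg_model`),
#'   `block_tests` (a `permutation_result` table or `NULL`), and
#'   `dissociation` (signs and significance of the focal effects).
#' @export
analyze_cohort <- function(seg_tab, blocks_long = NULL, covariates_tab,
                           n_perm = 1000, seed = 1L) {
  dat <- merge(seg_tab, covariates_tab, by = "subject_id")
  covs <- c("gender", "mean_fd_post", "education")
  if (nrow(dat) < length(covs) + 5)
    stop("insufficient subjects for inference: n = ", nrow(dat))

  models <- list(
    global = fit_ols(dat, "global", c("age", "cdr"), covs),
    assoc = fit_ols(dat, "assoc", c("age", "cdr"), covs),
    sensorimotor = fit_ols(dat, "sensorimotor", c("age", "cdr"), covs),
    mean_within = fit_ols(dat, "mean_within", c("age", "cdr"), covs),
    mean_between = fit_ols(dat, "mean_between", c("age", "cdr"), covs)
  )

  # within-subject contrasts: system type; interaction type
  long_type <- rbind(
    data.frame(dat[c("subject_id", "age", "cdr", covs)],
               condition = "association", outcome = dat$assoc),
    data.frame(dat[c("subject_id", "age", "cdr", covs)],
               condition = "sensory-motor", outcome = dat$sensorimotor))
  long_int <- rbind(
    data.frame(dat[c("subject_id", "age", "cdr", covs)],
               condition = "within", outcome = dat$mean_within),
    data.frame(dat[c("subject_id", "age", "cdr", covs)],
               condition = "between", outcome = dat$mean_between))
  models$age_by_system_type <- fit_interaction_mixed(
    long_type, "outcome", "condition", covariates = covs,
    scheme = "age_condition")
  models$cdr_by_system_type <- fit_interaction_mixed(
    long_type, "outcome", "condition", covariates = covs,
    scheme = "cdr_condition")
  models$cdr_by_interaction_type <- fit_interaction_mixed(
    long_int, "outcome", "condition", covariates = covs,
    scheme = "cdr_condition")

  block_tests <- NULL
  if (!is.null(blocks_long) && nrow(blocks_long)) {
    blocks_long$block <- paste(blocks_long$system_a, blocks_long$system_b,
                               sep = "|")
    wide <- stats::reshape(
      blocks_long[c("subject_id", "block", "mean_z")],
      idvar = "subject_id", timevar = "block", direction = "wide")
    bm <- as.matrix(wide[, -1, drop = FALSE])
    colnames(bm) <- sub("^mean_z\\.", "", colnames(bm))
    rownames(bm) <- wide$subject_id
    bdat <- dat[match(wide$subject_id, dat$subject_id), ]
    block_tests <- block_permutation_test(
      bm, bdat, focal = "cdr", covariates = c("age", covs),
      n_perm = n_perm, seed = seed)
  }

  term_sig <- function(model, term) {
    row <- model_term(model, term)
    list(beta = row$beta, p = row$p, significant = row$p < 0.05)
  }
  dissociation <- list(
    age_on_assoc = term_sig(models$assoc, "age"),
    age_on_sensorimotor = term_sig(models$sensorimotor, "age"),
    cdr_on_assoc = term_sig(models$assoc, "cdr"),
    cdr_on_sensorimotor = term_sig(models$sensorimotor, "cdr"),
    cdr_on_between = term_sig(models$mean_between, "cdr"),
    age_on_within = term_sig(models$mean_within, "age")
  )
  list(models = models, block_tests = block_tests,
       dissociation = dissociation)
}

#' @export
print.run_report <- function(x, ...) {
  cat("netseg run report (seed", x$master_seed, ")\n")
  cat(sprintf("  subjects: %d simulated, %d excluded by QC, %d analyzed\n",
              x$counts$simulated, x$counts$qc_excluded, x$counts$analyzed))
  d <- x$dissociation
  cat(sprintf("  age -> association segregation:    beta %+0.5f (p %.3g)\n",
              d$age_on_assoc$beta, d$age_on_assoc$p))
  cat(sprintf("  age -> sensory-motor segregation:  beta %+0.5f (p %.3g)\n",
              d$age_on_sensorimotor$beta, d$age_on_sensorimotor$p))
  cat(sprintf("  cdr -> mean between-system z:      beta %+0.5f (p %.3g)\n",
              d$cdr_on_between$beta, d$cdr_on_between$p))
  invisible(x)
}
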