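#' Multiple linear regression with partial r
#'
#' Ordinary least squares of a per-subject outcome on focal predictors
#' (typically age and CDR, with CDR coded as a continuous variable) plus
#' nuisance covariates (gender, post-scrubbing head motion, education,
#' optionally pulse and respiration). For every term the partial
#' correlation is computed as \eqn{t / \sqrt{t^2 + df}} with the residual
#' degrees of freedom, and a two-sided p-value from the t distribution.
#'
#' @param data data.frame containing all variables.
#' @param outcome name of the outcome column.
#' @param focal character vector of focal predictor names.
#' @param covariates character vector of covariate names (may be empty).
#' @param interactions optional character vector of interaction terms
#'   (e.g. `"age:cdr"`) appended to the formula.
#' @return object of class `netseg_model`: list with `terms` (data.frame:
#'   `term`, `beta`, `ci_lo`, `ci_hi`, `t`, `df`, `partial_r`, `p`),
#'   `r2`, `adj_r2`, `n`, `formula`, and the underlying `fit`.
#' @export
fit_ols <- function(data, outcome, focal, covariates = character(),
                    interactions = NULL) {
  rhs <- c(focal, covariates, interactions)
  if (!length(rhs)) stop("no predictors supplied")
  vars <- unique(unlist(strsplit(c(outcome, setdiff(rhs, interactions)),
                                 ":", fixed = TRUE)))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("variables not found: ", paste(missing_vars, collapse = ", "))
  data <- stats::na.omit(data[, unique(c(outcome, vars)), drop = FALSE])
  f <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  mm <- stats::model.matrix(f, data)
  if (nrow(data) <= ncol(mm) + 2)
    stop("insufficient subjects: n = ", nrow(data),
         " for ", ncol(mm), " model terms")
  if (qr(mm)$rank < ncol(mm)) {
    q <- qr(mm)
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("collinear design; offending term(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(f, data = data)
  s <- summary(fit)
  co <- s$coefficients
  df <- fit$df.residual
  ci <- stats::confint(fit)
  terms <- data.frame(
    term = rownames(co),
    beta = co[, "Estimate"],
    ci_lo = ci[, 1],
    ci_hi = ci[, 2],
    t = co[, "t value"],
    df = df,
    partial_r = co[, "t value"] / sqrt(co[, "t value"]^2 + df),
    p = co[, "Pr(>|t|)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(list(terms = terms, r2 = s$r.squared,
                 adj_r2 = s$adj.r.squared, n = nrow(data),
                 formula = deparse(f), fit = fit),
            class = "netseg_model")
}

#' @export
print.netseg_model <- function(x, digits = 4, ...) {
  cat(x$formula, "  (n =", x$n, ")\n")
  print(format(x$terms, digits = digits), row.names = FALSE)
  cat(sprintf("R2 = %.4f, adjusted R2 = %.4f\n", x$r2, x$adj_r2))
  if (!is.null(x$marginal_r2))
    cat(sprintf("marginal R2 = %.4f, conditional R2 = %.4f\n",
                x$marginal_r2, x$conditional_r2))
  invisible(x)
}

# term-level extractor used throughout reports/tests
#' Extract one term's row from a fitted model
#' @param model a `netseg_model`.
#' @param term term name as it appears in `model$terms$term`.
#' @return one-row data.frame.
#' @export
model_term <- function(model, term) {
  row <- model$terms[model$terms$term == term, ]
  if (!nrow(row)) stop("term not found: ", term)
  row
}

#' Random-intercept mixed model for within-subject contrasts
#'
#' Fits a linear mixed-effects model to a long table with exactly two
#' rows per subject (one per level of a within-subject `condition`, e.g.
#' system type = association vs sensory-motor, or interaction type =
#' within vs between), with a random intercept per subject. Three model
#' schemes mirror the staged analysis: the `"three_way"` model includes
#' the age x CDR x condition interaction; `"age_condition"` tests
#' age x condition controlling for CDR; `"cdr_condition"` tests
#' CDR x condition controlling for age. Covariates enter as
#' between-subject main effects.
#'
#' Degrees of freedom use the containment (between-within) rule:
#' within-subject terms get `n_obs - n_subjects - q_within`, between-
#' subject terms `n_subjects - q_between - 1`. Marginal and conditional
#' R-squared follow the variance-partition formulation for mixed models
#' (fixed-effect variance over total, and fixed plus random over total).
#'
#' @param long data.frame with columns `subject_id`, the outcome, the
#'   condition factor, focal predictors, covariates.
#' @param outcome outcome column name.
#' @param condition name of the two-level within-subject factor.
#' @param focal character vector, typically `c("age", "cdr")`.
#' @param covariates character vector of between-subject covariates.
#' @param scheme one of `"three_way"`, `"age_condition"`,
#'   `"cdr_condition"` (the latter two require `focal` to contain the
#'   named variable, with the other focal variable controlled as a main
#'   effect).
#' @return a `netseg_model` whose `terms` carry containment df, plus
#'   `marginal_r2` and `conditional_r2`.
#' @export
fit_interaction_mixed <- function(long, outcome, condition,
                                  focal = c("age", "cdr"),
                                  covariates = character(),
                                  scheme = c("age_condition",
                                             "cdr_condition",
                                             "three_way")) {
  scheme <- match.arg(scheme)
  need <- unique(c("subject_id", outcome, condition, focal, covariates))
  missing_vars <- setdiff(need, names(long))
  if (length(missing_vars))
    stop("variables not found: ", paste(missing_vars, collapse = ", "))
  long <- stats::na.omit(long[, need, drop = FALSE])
  tab <- table(long$subject_id)
  lev <- unique(long[[condition]])
  if (length(lev) != 2 || any(tab != 2))
    stop("unbalanced conditions: need exactly 2 condition rows per subject")
  long[[condition]] <- factor(long[[condition]])

  rhs <- switch(scheme,
    three_way = paste0(focal[1], " * ", focal[2], " * ", condition),
    age_condition = paste0("age * ", condition, " + ",
                           paste(setdiff(focal, "age"), collapse = " + ")),
    cdr_condition = paste0("cdr * ", condition, " + ",
                           paste(setdiff(focal, "cdr"), collapse = " + "))
  )
  if (length(covariates))
    rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  f <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | subject_id)"))
  fit <- lme4::lmer(f, data = long, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      check.scaleX = "ignore"))

  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  x <- lme4::getME(fit, "X")
  n_subj <- length(unique(long$subject_id))
  n_obs <- nrow(long)

  # containment df: does the design column vary within subjects?
  within_col <- apply(x, 2, function(col)
    any(tapply(col, long$subject_id, function(v) max(v) - min(v)) > 0))
  q_within <- sum(within_col)
  q_between <- sum(!within_col) - 1  # minus intercept
  df <- ifelse(within_col, n_obs - n_subj - q_within,
               n_subj - q_between - 1)

  tval <- fe / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tq <- stats::qt(0.975, df)
  terms <- data.frame(
    term = names(fe), beta = unname(fe),
    ci_lo = unname(fe - tq * se), ci_hi = unname(fe + tq * se),
    t = unname(tval), df = unname(df),
    partial_r = unname(tval / sqrt(tval^2 + df)),
    p = unname(pval), stringsAsFactors = FALSE
  )

  var_fixed <- stats::var(as.vector(x %*% fe))
  var_rand <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual" &
                            (is.na(vc$var1) | vc$var1 == "(Intercept)")])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  total <- var_fixed + var_rand + var_resid
  structure(list(terms = terms,
                 r2 = NA_real_, adj_r2 = NA_real_,
                 marginal_r2 = var_fixed / total,
                 conditional_r2 = (var_fixed + var_rand) / total,
                 n = n_subj, formula = deparse(f), fit = fit),
            class = "netseg_model")
}

#' Covariate-controlled block permutation test
#'
#' For each system-by-system block, the observed regression coefficient
#' of the focal variable (e.g. CDR) on the block mean is compared with a
#' permutation null built by the Freedman-Lane scheme: the outcome is
#' residualized on the covariates alone, the residuals are permuted
#' across participants, re-added to the covariate fit, and the full model
#' is refit. This honors the covariates under the null, which a naive
#' label shuffle would not. The two-sided p-value is
#' `(1 + #permutations with |beta*| >= |beta_obs|) / (n_perm + 1)`, so it
#' can never be exactly zero. Blocks are flagged at p < 0.05 uncorrected
#' and after Benjamini-Hochberg FDR correction across all tested blocks.
#'
#' @param blocks n_subjects x n_blocks numeric matrix or data.frame of
#'   per-subject block means (columns named by block).
#' @param data data.frame with the focal variable and covariates, rows
#'   aligned with `blocks`.
#' @param focal name of the focal variable (constant focal is an error).
#' @param covariates character vector of covariate names.
#' @param n_perm number of permutations (>= 100; the reference analysis
#'   uses 1000).
#' @param seed integer seed; identical seeds give identical results.
#' @return object of class `permutation_result`: data.frame `table` with
#'   `block`, `beta`, `p`, `p_fdr`, `uncorrected_significant`,
#'   `fdr_significant`, plus `n_perm` and `seed`.
#' @export
block_permutation_test <- function(blocks, data, focal,
                                   covariates = character(),
                                   n_perm = 1000, seed = 1L) {
  blocks <- as.matrix(blocks)
  if (is.null(colnames(blocks)))
    colnames(blocks) <- paste0("block", seq_len(ncol(blocks)))
  if (nrow(blocks) != nrow(data))
    stop("blocks and data must have the same number of rows")
  if (n_perm < 100) stop("n_perm must be >= 100")
  keep <- stats::complete.cases(data[, c(focal, covariates), drop = FALSE]) &
    stats::complete.cases(blocks)
  blocks <- blocks[keep, , drop = FALSE]
  data <- data[keep, , drop = FALSE]
  n <- nrow(blocks)
  fvals <- data[[focal]]
  if (length(unique(fvals)) < 2)
    stop("focal variable '", focal, "' is constant")

  x_red <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", covariates), collapse = " + "))),
    data)
  x_full <- cbind(x_red, focal = if (is.numeric(fvals)) fvals
                  else as.numeric(factor(fvals)))
  if (qr(x_full)$rank < ncol(x_full))
    stop("collinear design in permutation test")

  proj_full <- solve(crossprod(x_full), t(x_full))  # k x n
  focal_row <- nrow(proj_full)
  beta_obs <- drop(proj_full[focal_row, , drop = FALSE] %*% blocks)

  # Freedman-Lane: residualize on covariates, permute residuals
  hat_red <- x_red %*% solve(crossprod(x_red), t(x_red))
  fitted_red <- hat_red %*% blocks
  resid_red <- blocks - fitted_red

  set.seed(seed)
  exceed <- numeric(ncol(blocks))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    y_star <- fitted_red + resid_red[perm, , drop = FALSE]
    beta_star <- drop(proj_full[focal_row, , drop = FALSE] %*% y_star)
    exceed <- exceed + (abs(beta_star) >= abs(beta_obs))
  }
  p <- (1 + exceed) / (n_perm + 1)
  p_fdr <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(block = colnames(blocks), beta = unname(beta_obs),
                    p = unname(p), p_fdr = unname(p_fdr),
                    uncorrected_significant = unname(p < 0.05),
                    fdr_significant = unname(p_fdr <= 0.05 & p < 0.05),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("block permutation test:", x$n_perm, "permutations, seed", x$seed,
      "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up false-discovery-rate control at level `q`: with ordered
#' p-values, reject hypotheses 1..k where k is the largest index with
#' `p_(k) <= k q / m`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical vector of rejection flags.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Bonferroni correction for post hoc tests
#'
#' @param p numeric vector of uncorrected p-values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return corrected p-values `min(1, m * p)`.
#' @export
bonferroni_posthoc <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Categorical CDR grouping
#'
#' Secondary analyses treat dementia severity as a category; the sparse
#' top of the scale is collapsed: groups are CDR 0, CDR 0.5, and CDR 1-2.
#'
#' @param cdr numeric CDR scores in \{0, 0.5, 1, 2\}.
#' @return factor with levels `"0"`, `"0.5"`, `"1-2"`.
#' @export
cdr_category <- function(cdr) {
  if (!all(cdr %in% c(0, 0.5, 1, 2)))
    stop("CDR values must be in {0, 0.5, 1, 2}")
  factor(ifelse(cdr == 0, "0", ifelse(cdr == 0.5, "0.5", "1-2")),
         levels = c("0", "0.5", "1-2"))
}

#' Pairwise post hoc group comparisons with Bonferroni correction
#'
#' Welch t-tests between all pairs of groups of `group`, Bonferroni
#' corrected across the family of pairwise comparisons.
#'
#' @param outcome numeric outcome per subject.
#' @param group factor of group labels (e.g. [cdr_category()]).
#' @return data.frame: `group_a`, `group_b`, `t`, `df`, `p`,
#'   `p_bonferroni`.
#' @export
posthoc_group_tests <- function(outcome, group) {
  group <- droplevels(as.factor(group))
  levs <- levels(group)
  if (length(levs) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(levs, 2)
  res <- apply(pairs, 2, function(pr) {
    tt <- stats::t.test(outcome[group == pr[1]], outcome[group == pr[2]])
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  })
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    t(res), stringsAsFactors = FALSE)
  out$p_bonferroni <- bonferroni_posthoc(out$p, m = ncol(pairs))
  out
}
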