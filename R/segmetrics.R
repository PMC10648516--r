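#' Brain system segregation and its decompositions
#'
#' Global brain system segregation is the pooled node-pair statistic
#' \deqn{(\bar{Z}_w - \bar{Z}_b) / \bar{Z}_w} where \eqn{\bar{Z}_w} is the
#' mean Fisher-z correlation over all within-system node pairs (pooled
#' across systems) and \eqn{\bar{Z}_b} the mean over all between-system
#' node pairs. It equals 1 when every system is disconnected from every
#' other (all between-system values zero) and 0 when within and between
#' means coincide. System-type segregation (see
#' [system_type_segregation()]) instead uses grand means of per-system
#' means; the two readings differ for unequal system sizes and both are
#' provided as distinct code paths.
#'
#' @param m a `connectivity_matrix` with negatives already zeroed (an
#'   error otherwise).
#' @param partition a [system_partition()]; systems typed `"unassigned"`
#'   are excluded from every pool.
#' @return object of class `segregation_result`: a list with
#'   `global_segregation`, `mean_within`, `mean_between`,
#'   `n_within_pairs`, `n_between_pairs`, `assoc_segregation`,
#'   `sensorimotor_segregation`, `per_system_within` (Ws),
#'   `per_system_between` (Bs).
#' @export
system_segregation <- function(m, partition) {
  pools <- .pair_pools(m, partition)
  mw <- mean(pools$within_values)
  mb <- mean(pools$between_values)
  if (!is.finite(mw) || mw == 0)
    stop("undefined segregation: pooled mean within-system value is 0")
  per_sys <- .per_system_means(m, partition)
  res <- list(
    global_segregation = (mw - mb) / mw,
    mean_within = mw,
    mean_between = mb,
    n_within_pairs = length(pools$within_values),
    n_between_pairs = length(pools$between_values),
    assoc_segregation = tryCatch(
      system_type_segregation(m, partition, "association"),
      error = function(e) NA_real_),
    sensorimotor_segregation = tryCatch(
      system_type_segregation(m, partition, "sensory-motor"),
      error = function(e) NA_real_),
    per_system_within = per_sys$within,
    per_system_between = per_sys$between
  )
  class(res) <- "segregation_result"
  res
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "system segregation: global %.4f (assoc %.4f, sensory-motor %.4f)\n",
    x$global_segregation, x$assoc_segregation, x$sensorimotor_segregation))
  cat(sprintf("  mean within z %.4f (%d pairs), mean between z %.4f (%d pairs)\n",
              x$mean_within, x$n_within_pairs,
              x$mean_between, x$n_between_pairs))
  invisible(x)
}

# internal: system labels aligned to matrix order, with size check
.sys_for_matrix <- function(m, partition) {
  sys <- .partition_systems(partition, node_ids = rownames(m))
  if (length(sys) != nrow(m))
    stop("matrix size does not match partition node count")
  sys
}

# internal: checks + aligned system labels + upper-triangle pair values
.pair_pools <- function(m, partition) {
  if (isFALSE(attr(m, "negatives_zeroed")) ||
      any(m[!is.na(m)] < 0))
    stop("negative values present: apply zero_negatives() first")
  sys <- .sys_for_matrix(m, partition)
  n <- nrow(m)
  ut <- upper.tri(m)
  same <- outer(sys, sys, "==")        # NA where either node unassigned
  within <- ut & !is.na(same) & same
  between <- ut & !is.na(same) & !same
  if (!any(within) || !any(between))
    stop("need at least one within-system and one between-system pair")
  list(sys = sys,
       within_values = m[within],
       between_values = m[between])
}

# internal: per-system mean within (Ws) and mean between (Bs) values
.per_system_means <- function(m, partition) {
  sys <- .sys_for_matrix(m, partition)
  systems <- unique(sys[!is.na(sys)])
  ws <- bs <- stats::setNames(rep(NA_real_, length(systems)), systems)
  for (s in systems) {
    inside <- which(!is.na(sys) & sys == s)
    outside <- which(!is.na(sys) & sys != s)
    if (length(inside) >= 2) {
      sub <- m[inside, inside]
      ws[s] <- mean(sub[upper.tri(sub)])
    }
    if (length(outside) >= 1)
      bs[s] <- mean(m[inside, outside])
  }
  list(within = ws, between = bs)
}

#' System-type segregation (grand mean of per-system means)
#'
#' For each system S of the requested type with at least two nodes,
#' compute Ws (mean z over node pairs inside S) and Bs (mean z over pairs
#' from S to all other assigned systems, of any type). The type
#' segregation is \eqn{(\bar{W_s} - \bar{B_s}) / \bar{W_s}} with grand
#' means taken across the systems of that type - a mean of means, not a
#' pooled pair mean.
#'
#' @inheritParams system_segregation
#' @param type `"association"` or `"sensory-motor"`.
#' @return scalar segregation value.
#' @export
system_type_segregation <- function(m, partition,
                                    type = c("association", "sensory-motor")) {
  type <- match.arg(type)
  .pair_pools(m, partition)  # validates matrix + partition
  per_sys <- .per_system_means(m, partition)
  types <- .assigned_system_types(partition)
  sel <- names(types)[types == type]
  sel <- sel[!is.na(per_sys$within[sel])]  # systems with >= 2 nodes
  if (!length(sel))
    stop("no system of type '", type, "' with >= 2 nodes")
  gw <- mean(per_sys$within[sel])
  gb <- mean(per_sys$between[sel])
  if (!is.finite(gw) || gw == 0)
    stop("undefined segregation: grand mean within-system value is 0")
  (gw - gb) / gw
}

#' Mean within- and between-system network interactions
#'
#' Grand means, across all assigned systems with at least two nodes, of
#' the per-system mean within-system z (Ws) and per-system mean
#' between-system z (Bs) - the two outcome measures of the
#' interaction-type analysis.
#'
#' @inheritParams system_segregation
#' @return named numeric vector `c(mean_within_z, mean_between_z)`.
#' @export
mean_interactions <- function(m, partition) {
  .pair_pools(m, partition)
  per_sys <- .per_system_means(m, partition)
  sel <- names(per_sys$within)[!is.na(per_sys$within)]
  c(mean_within_z = mean(per_sys$within[sel]),
    mean_between_z = mean(per_sys$between[sel]))
}

#' System-by-system block matrix
#'
#' Symmetric S x S matrix of block means over node pairs: diagonal entries
#' are within-system block means (mean z over pairs inside the system;
#' `NA` for one-node systems), off-diagonal entries are between-system
#' block means (mean z over all node pairs spanning the two systems).
#' Unassigned-type systems are excluded; undefined blocks propagate as
#' `NA`, never as zero.
#'
#' @inheritParams system_segregation
#' @return matrix of class `block_matrix` with system labels as dimnames.
#' @export
block_matrix <- function(m, partition) {
  sys <- .sys_for_matrix(m, partition)
  systems <- partition$systems$system[partition$systems$type != "unassigned"]
  systems <- systems[systems %in% sys]
  k <- length(systems)
  out <- matrix(NA_real_, k, k, dimnames = list(systems, systems))
  for (i in seq_len(k)) {
    ni <- which(!is.na(sys) & sys == systems[i])
    if (length(ni) >= 2) {
      sub <- m[ni, ni]
      out[i, i] <- mean(sub[upper.tri(sub)])
    }
    if (i < k) for (j in (i + 1):k) {
      nj <- which(!is.na(sys) & sys == systems[j])
      out[i, j] <- out[j, i] <- mean(m[ni, nj])
    }
  }
  structure(out, class = c("block_matrix", "matrix", "array"))
}

#' Long-format view of a block matrix
#'
#' @param bm a [block_matrix()].
#' @return data.frame with columns `system_a`, `system_b`, `mean_z`, one
#'   row per unique block (within blocks have `system_a == system_b`).
#' @export
block_long <- function(bm) {
  systems <- rownames(bm)
  idx <- which(upper.tri(bm, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(system_a = systems[idx[, "row"]],
             system_b = systems[idx[, "col"]],
             mean_z = bm[idx],
             stringsAsFactors = FALSE)
}
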