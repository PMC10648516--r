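# Independent brute-force oracles and shared fixtures.
# The oracles enumerate node pairs with explicit double loops and never
# call the package's vectorized paths.

# small 2-system / 4-node partition: A = {n1, n2} assoc, B = {n3, n4} s-m
toy_partition_2x2 <- function() {
  system_partition(paste0("n", 1:4), c("A", "A", "B", "B"),
                   c(A = "association", B = "sensory-motor"))
}

# 3 systems of unequal size (3 + 2 + 2 nodes), mixed types
toy_partition_3sys <- function() {
  system_partition(paste0("n", 1:7),
                   c("A", "A", "A", "B", "B", "C", "C"),
                   c(A = "association", B = "association",
                     C = "sensory-motor"))
}

# symmetric z-matrix with NA diagonal from a within/between template
toy_block_matrix <- function(partition, within, between) {
  sys <- partition$nodes$system
  n <- length(sys)
  m <- matrix(NA_real_, n, n,
              dimnames = list(partition$nodes$node_id,
                              partition$nodes$node_id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m[i, j] <- if (sys[i] == sys[j]) within else between
  }
  structure(m, class = c("connectivity_matrix", "matrix", "array"),
            negatives_zeroed = all(c(within, between) >= 0))
}

# random nonnegative symmetric connectivity matrix for a partition
random_connectivity <- function(partition, seed) {
  set.seed(seed)
  n <- nrow(partition$nodes)
  m <- matrix(0, n, n)
  vals <- runif(n * (n - 1) / 2, 0, 1)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- NA_real_
  dimnames(m) <- list(partition$nodes$node_id, partition$nodes$node_id)
  structure(m, class = c("connectivity_matrix", "matrix", "array"),
            negatives_zeroed = TRUE)
}

# map node index -> system label (NA for unassigned), partition order
oracle_system_labels <- function(partition) {
  sys <- partition$nodes$system
  type <- partition$systems$type[match(sys, partition$systems$system)]
  sys[type == "unassigned"] <- NA
  sys
}

# pooled global segregation by exhaustive pair enumeration
oracle_global_segregation <- function(m, partition) {
  sys <- oracle_system_labels(partition)
  w <- c(); b <- c()
  n <- nrow(m)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (is.na(sys[i]) || is.na(sys[j])) next
    if (sys[i] == sys[j]) w <- c(w, m[i, j]) else b <- c(b, m[i, j])
  }
  (mean(w) - mean(b)) / mean(w)
}

# per-system Ws and Bs by enumeration
oracle_per_system <- function(m, partition) {
  sys <- oracle_system_labels(partition)
  systems <- unique(sys[!is.na(sys)])
  n <- nrow(m)
  ws <- bs <- setNames(rep(NA_real_, length(systems)), systems)
  for (s in systems) {
    wv <- c(); bv <- c()
    for (i in 1:n) for (j in 1:n) {
      if (i >= j || is.na(sys[i]) || is.na(sys[j])) next
      if (sys[i] == s && sys[j] == s) wv <- c(wv, m[i, j])
    }
    for (i in 1:n) for (j in 1:n) {
      if (i == j || is.na(sys[i]) || is.na(sys[j])) next
      if (sys[i] == s && sys[j] != s) bv <- c(bv, m[i, j])
    }
    if (length(wv)) ws[s] <- mean(wv)
    if (length(bv)) bs[s] <- mean(bv)
  }
  list(within = ws, between = bs)
}

oracle_type_segregation <- function(m, partition, type) {
  per <- oracle_per_system(m, partition)
  types <- setNames(partition$systems$type, partition$systems$system)
  sel <- names(per$within)[types[names(per$within)] == type &
                             !is.na(per$within)]
  gw <- mean(per$within[sel]); gb <- mean(per$between[sel])
  (gw - gb) / gw
}

oracle_mean_interactions <- function(m, partition) {
  per <- oracle_per_system(m, partition)
  sel <- names(per$within)[!is.na(per$within)]
  c(mean(per$within[sel]), mean(per$between[sel]))
}

oracle_block_matrix <- function(m, partition) {
  sys <- oracle_system_labels(partition)
  systems <- partition$systems$system[partition$systems$type != "unassigned"]
  k <- length(systems)
  out <- matrix(NA_real_, k, k, dimnames = list(systems, systems))
  n <- nrow(m)
  for (a in 1:k) for (b in 1:k) {
    vals <- c()
    for (i in 1:n) for (j in 1:n) {
      if (is.na(sys[i]) || is.na(sys[j])) next
      if (sys[i] != systems[a] || sys[j] != systems[b]) next
      if (a == b) { if (i < j) vals <- c(vals, m[i, j]) }
      else vals <- c(vals, m[i, j])
    }
    if (length(vals)) out[a, b] <- mean(vals)
  }
  out
}

# shared expensive replicate studies, computed once per test run
.study_cache <- new.env(parent = emptyenv())

cached_dissociation_study <- function() {
  if (is.null(.study_cache$dissoc)) {
    .study_cache$dissoc <- replicate_dissociation(
      n_reps = 50, n_subjects = 300, seed = 20260917, fit_mixed = TRUE)
  }
  .study_cache$dissoc
}

cached_calibration_study <- function() {
  if (is.null(.study_cache$calib)) {
    .study_cache$calib <- permutation_calibration(
      n_reps = 500, n_subjects = 150, n_perm = 200, seed = 41)
  }
  .study_cache$calib
}
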