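#' Average member time series into node time series
#'
#' Each node's signal is the arithmetic mean, per frame, of its member
#' (e.g. vertex) signals.
#'
#' @param member_ts frames x members numeric matrix.
#' @param membership character/factor vector of length `ncol(member_ts)`
#'   giving the node of each member.
#' @return frames x nodes matrix, columns named by node, in first-occurrence
#'   order of `membership`.
#' @export
average_members <- function(member_ts, membership) {
  member_ts <- as.matrix(member_ts)
  membership <- as.character(membership)
  if (length(membership) != ncol(member_ts))
    stop("membership length must equal member count")
  if (anyNA(membership)) stop("every member must map to a node")
  nodes <- unique(membership)
  out <- vapply(nodes, function(nd)
    rowMeans(member_ts[, membership == nd, drop = FALSE]),
    numeric(nrow(member_ts)))
  colnames(out) <- nodes
  out
}

#' Fisher-z connectivity matrix
#'
#' Pairwise Pearson correlations of the node time series, Fisher
#' z-transformed (`atanh`), with `r` clipped to |r| <= 1 - 1e-7 so that
#' degenerate (duplicated) signals stay finite. The diagonal is
#' structurally excluded: it is stored as `NA` and no downstream
#' computation touches it.
#'
#' @param node_ts frames x nodes numeric matrix (>= 3 frames); columns may
#'   be named with node ids.
#' @return symmetric matrix of class `connectivity_matrix` with `NA`
#'   diagonal.
#' @export
correlation_matrix <- function(node_ts) {
  node_ts <- as.matrix(node_ts)
  if (nrow(node_ts) < 3) stop("need >= 3 frames to correlate")
  v <- apply(node_ts, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(node_ts)[v == 0] %||% which(v == 0)
    stop("zero-variance node(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(node_ts)
  clip <- 1 - 1e-7
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- NA_real_
  structure(z, class = c("connectivity_matrix", "matrix", "array"),
            negatives_zeroed = FALSE)
}

#' Zero negative connectivity values
#'
#' Global signal regression can introduce spurious negative correlations;
#' every negative entry is therefore set to zero before segregation is
#' computed. No edge-density thresholding is applied (the segregation
#' statistic does not require a sparse matrix).
#'
#' @param m a `connectivity_matrix` (or plain symmetric matrix).
#' @return the matrix with all negative entries replaced by 0 and
#'   attribute `negatives_zeroed` set.
#' @export
zero_negatives <- function(m) {
  m[!is.na(m) & m < 0] <- 0
  attr(m, "negatives_zeroed") <- TRUE
  m
}

#' Read / write a connectivity matrix as TSV
#'
#' Plain TSV with a header row of node ids (language-neutral, diffable).
#' The `NA` diagonal round-trips.
#'
#' @param m a `connectivity_matrix`.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  tab <- as.data.frame(unclass(m))
  if (is.null(colnames(m)))
    colnames(tab) <- sprintf("node%03d", seq_len(ncol(m)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab)
  rownames(m) <- colnames(m)
  zeroed <- all(m[!is.na(m)] >= 0)
  structure(m, class = c("connectivity_matrix", "matrix", "array"),
            negatives_zeroed = zeroed)
}

#' Build a connectivity matrix from a selected time series
#'
#' Thin composition used by the pipeline: correlation, Fisher z,
#' negative zeroing.
#'
#' @param ts a [bold_timeseries()] (typically at stage `"selected"`).
#' @return a `connectivity_matrix` with negatives zeroed.
#' @export
build_network <- function(ts) {
  stopifnot(inherits(ts, "bold_ts"))
  zero_negatives(correlation_matrix(ts$data))
}
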