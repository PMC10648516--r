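#' BOLD time-series container
#'
#' Frames x nodes signal matrix with repetition time and per-frame status.
#' The object carries a `stage` marker recording how far through the
#' ordered denoising chain it has travelled; each denoising operation
#' checks that its predecessor has run, so stages cannot be applied out of
#' order.
#'
#' @param data numeric matrix, frames in rows, nodes in columns.
#' @param tr repetition time in seconds (> 0).
#' @param frame_status character vector, one of `"clean"`, `"censored"`,
#'   `"interpolated"` per frame; defaults to all `"clean"`.
#' @param stage internal pipeline stage marker.
#' @return object of class `bold_ts`.
#' @export
bold_timeseries <- function(data, tr, frame_status = NULL, stage = "raw") {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("time-series data must be a finite numeric matrix")
  if (length(tr) != 1 || tr <= 0) stop("tr must be a positive scalar")
  if (is.null(frame_status)) frame_status <- rep("clean", nrow(data))
  if (length(frame_status) != nrow(data))
    stop("frame_status length must equal frame count")
  if (!all(frame_status %in% c("clean", "censored", "interpolated")))
    stop("invalid frame_status values")
  structure(list(data = data, tr = tr, frame_status = frame_status,
                 stage = stage),
            class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat("bold_ts:", nrow(x$data), "frames x", ncol(x$data), "nodes; TR",
      x$tr, "s; stage:", x$stage, ";",
      sum(x$frame_status == "clean"), "clean frames\n")
  invisible(x)
}

#' @export
n_frames <- function(ts) UseMethod("n_frames")
#' @export
n_frames.bold_ts <- function(ts) nrow(ts$data)

.denoise_stages <- c("raw", "detrended", "regressed", "scrubbed",
                     "filtered", "trimmed", "selected")

.require_stage <- function(ts, expected, op) {
  stopifnot(inherits(ts, "bold_ts"))
  if (!identical(ts$stage, expected))
    stop(sprintf(
      "pipeline order violation: %s requires stage '%s' but input is at '%s'",
      op, expected, ts$stage))
}

.advance_stage <- function(ts, stage) { ts$stage <- stage; ts }

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) and of the three rotations
#' converted to arc length on a sphere of `head_radius` mm. The first
#' frame has FD 0 by convention.
#'
#' @param motion frames x 6 numeric matrix: translations (mm) in columns
#'   1-3, rotations (radians) in columns 4-6.
#' @param head_radius sphere radius (mm) for rotation conversion.
#' @return numeric vector of per-frame FD, mm.
#' @examples
#' m <- matrix(0, 10, 6)
#' m[5, 1] <- 0.1                  # single 0.1 mm translation step
#' compute_fd(m)[5]                # 0.1
#' @export
compute_fd <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (!is.numeric(motion) || ncol(motion) != 6 || any(!is.finite(motion)))
    stop("format error: motion must be a finite numeric frames x 6 matrix")
  if (nrow(motion) < 2) stop("need >= 2 frames to compute FD")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Assemble the nuisance design
#'
#' Columns: global signal (mean over all nodes), the tissue surrogate
#' channels (white matter, ventricle), their backward differences, the six
#' rigid-body parameters, their backward differences, and the squares of
#' those twelve (the Friston-24 motion set). With two tissue surrogates
#' this yields 2 x 3 + 24 = 30 columns. Degenerate columns (zero variance
#' or exact duplicates) are dropped with a warning so the design stays
#' full rank; no constant column is included (the detrend step removes
#' means).
#'
#' @param ts a [bold_timeseries()].
#' @param motion frames x 6 motion parameter matrix.
#' @param tissue_surrogates frames x k matrix of tissue signals (e.g.
#'   white-matter and ventricle means), or `NULL` for none.
#' @return numeric design matrix with named columns.
#' @export
build_nuisance <- function(ts, motion, tissue_surrogates = NULL) {
  stopifnot(inherits(ts, "bold_ts"))
  nf <- n_frames(ts)
  motion <- as.matrix(motion)
  if (nrow(motion) != nf)
    stop("frame-count mismatch between time series and motion")
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  gs <- rowMeans(ts$data)
  tissues <- cbind(gs = gs)
  if (!is.null(tissue_surrogates)) {
    tissue_surrogates <- as.matrix(tissue_surrogates)
    if (nrow(tissue_surrogates) != nf)
      stop("frame-count mismatch between time series and tissue surrogates")
    if (is.null(colnames(tissue_surrogates)))
      colnames(tissue_surrogates) <-
        paste0("tissue", seq_len(ncol(tissue_surrogates)))
    tissues <- cbind(tissues, tissue_surrogates)
  }
  bdiff <- function(m) rbind(0, diff(m))
  if (is.null(colnames(motion)))
    colnames(motion) <- paste0("mot", 1:6)
  dmot <- bdiff(motion)
  x <- cbind(tissues, bdiff(tissues), motion, dmot, motion^2, dmot^2)
  colnames(x) <- c(colnames(tissues),
                   paste0("d.", colnames(tissues)),
                   colnames(motion),
                   paste0("d.", colnames(motion)),
                   paste0(colnames(motion), ".sq"),
                   paste0("d.", colnames(motion), ".sq"))
  keep <- apply(x, 2, stats::sd) > 0
  dup <- duplicated(t(x))
  drop <- !keep | dup
  if (any(drop)) {
    warning("dropping degenerate nuisance column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
  }
  x
}

#' Demean and detrend node signals
#'
#' Removes the per-node least-squares line (intercept and linear trend in
#' frame index). First stage of the denoising chain.
#'
#' @param ts a [bold_timeseries()] at stage `"raw"`.
#' @return detrended `bold_ts`.
#' @export
demean_detrend <- function(ts) {
  .require_stage(ts, "raw", "demean_detrend")
  if (n_frames(ts) < 3) stop("need >= 3 frames to detrend")
  t_idx <- seq_len(n_frames(ts))
  x <- cbind(1, t_idx - mean(t_idx))
  ts$data <- stats::lm.fit(x, ts$data)$residuals
  dimnames(ts$data) <- list(NULL, colnames(ts$data))
  .advance_stage(ts, "detrended")
}

#' Nuisance regression
#'
#' Removes the nuisance design from every node signal by multiple
#' regression. Coefficients are estimated on non-censored frames only
#' (high-motion frames should not drive nuisance fits) and residuals are
#' computed for all frames, so frames later replaced by interpolation stay
#' consistent through filtering. Residuals on clean frames are orthogonal
#' to every regressor. An intercept is included internally.
#'
#' @param ts a [bold_timeseries()] at stage `"detrended"`.
#' @param nuisance design matrix from [build_nuisance()].
#' @param censor_mask logical per frame, `TRUE` for frames to exclude from
#'   the fit (e.g. `fd > 0.3`); `NULL` for none.
#' @return regressed `bold_ts`.
#' @export
regress_nuisance <- function(ts, nuisance, censor_mask = NULL) {
  .require_stage(ts, "detrended", "regress_nuisance")
  nuisance <- as.matrix(nuisance)
  nf <- n_frames(ts)
  if (nrow(nuisance) != nf) stop("frame-count mismatch in nuisance design")
  if (is.null(censor_mask)) censor_mask <- rep(FALSE, nf)
  if (length(censor_mask) != nf) stop("censor_mask length mismatch")
  fit_rows <- !censor_mask
  if (sum(fit_rows) <= ncol(nuisance) + 1)
    stop("too few clean frames to fit the nuisance design")
  x <- cbind(`(Intercept)` = 1, nuisance)
  qx <- qr(x[fit_rows, , drop = FALSE])
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient nuisance design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, ts$data[fit_rows, , drop = FALSE])
  ts$data <- ts$data - x %*% beta
  .advance_stage(ts, "regressed")
}

#' Scrub high-motion frames with interpolation
#'
#' Frames whose framewise displacement exceeds `threshold` are flagged and
#' their values replaced by linear interpolation between the flanking
#' clean frames (nearest clean value at the edges), so that temporal
#' filtering can run on a gap-free series. The interpolated frames are
#' removed after filtering by [drop_interpolated()].
#'
#' @param ts a [bold_timeseries()] at stage `"regressed"`.
#' @param fd per-frame framewise displacement (mm), from [compute_fd()].
#' @param threshold scrubbing threshold, mm (default 0.3).
#' @return scrubbed `bold_ts` with `frame_status` updated.
#' @export
censor_and_interpolate <- function(ts, fd, threshold = 0.3) {
  .require_stage(ts, "regressed", "censor_and_interpolate")
  nf <- n_frames(ts)
  if (length(fd) != nf) stop("fd length must equal frame count")
  bad <- fd > threshold
  if (all(bad)) stop("all frames exceed the motion threshold")
  if (any(bad)) {
    good <- which(!bad)
    for (j in seq_len(ncol(ts$data))) {
      ts$data[bad, j] <- stats::approx(good, ts$data[good, j],
                                       xout = which(bad), rule = 2)$y
    }
    ts$frame_status[bad] <- "interpolated"
  }
  .advance_stage(ts, "scrubbed")
}

# order-2 Butterworth biquad coefficients (bilinear transform, Q = 1/sqrt2)
.butter2 <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / sqrt(2)
  cw <- cos(w0)
  if (type == "low") {
    b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
  } else {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  }
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# direct-form-II-transposed IIR filter with steady-state initial
# conditions scaled to the first sample, so a constant input yields its
# steady-state response immediately (no slow start-up transient)
.iir <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  k <- sum(b) / sum(a)          # DC gain
  z1 <- (k - b[1]) * x[1]
  z2 <- (b[3] - a[3] * k) * x[1]
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * y[i] + z2
    z2 <- b[3] * x[i] - a[3] * y[i]
  }
  y
}

# zero-phase filtering: odd-reflection padding, forward and reverse passes
.filtfilt <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1, 24)
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  ext <- c(pre, x, post)
  y <- .iir(b, a, ext)
  y <- rev(.iir(b, a, rev(y)))
  y[(p + 1):(p + n)]
}

#' Zero-phase bandpass filter
#'
#' Cascade of second-order Butterworth high-pass (at `low`) and low-pass
#' (at `high`) sections, each applied forward and backward (zero phase).
#' Defaults 0.009-0.08 Hz, the standard resting-state band. The combined
#' amplitude response is at least 0.9 inside the band and at most 0.1 one
#' octave outside it.
#'
#' @param ts a [bold_timeseries()] at stage `"scrubbed"`.
#' @param low,high band edges, Hz; must satisfy 0 < low < high < Nyquist.
#' @return filtered `bold_ts`.
#' @export
bandpass <- function(ts, low = 0.009, high = 0.08) {
  .require_stage(ts, "scrubbed", "bandpass")
  fs <- 1 / ts$tr
  if (!(0 < low && low < high && high < fs / 2))
    stop(sprintf("infeasible band [%g, %g] Hz for TR %g s (Nyquist %g Hz)",
                 low, high, ts$tr, fs / 2))
  hp <- .butter2(low, fs, "high")
  lp <- .butter2(high, fs, "low")
  ts$data <- apply(ts$data, 2, function(x)
    .filtfilt(lp$b, lp$a, .filtfilt(hp$b, hp$a, x)))
  .advance_stage(ts, "filtered")
}

#' Remove interpolated frames
#'
#' Keeps only clean frames (order preserved); the interpolated frames
#' existed solely to keep the series gap-free during regression and
#' filtering.
#'
#' @param ts a [bold_timeseries()] at stage `"filtered"`.
#' @return trimmed `bold_ts` containing clean frames only. The original
#'   frame indices of the retained frames are stored in attribute
#'   `"kept_frames"` of the data matrix.
#' @export
drop_interpolated <- function(ts) {
  .require_stage(ts, "filtered", "drop_interpolated")
  keep <- ts$frame_status == "clean"
  kept <- which(keep)
  ts$data <- ts$data[keep, , drop = FALSE]
  attr(ts$data, "kept_frames") <- kept
  ts$frame_status <- ts$frame_status[keep]
  .advance_stage(ts, "trimmed")
}

#' Quality control and clean-frame selection
#'
#' Subjects with fewer than `min_frames` clean frames after scrubbing are
#' excluded (a verdict, not an error). Otherwise exactly the first
#' `n_select` clean frames are retained, controlling for the variable
#' number of clean frames across subjects. Mean post-scrubbing FD over the
#' selected frames is recorded when `fd` is supplied.
#'
#' @param ts a [bold_timeseries()] at stage `"trimmed"`.
#' @param min_frames minimum clean frames to pass QC (default 100).
#' @param n_select number of clean frames retained for network analysis
#'   (default 100).
#' @param fd optional full-length FD vector (pre-trim frame indexing) used
#'   to compute `mean_fd_post`.
#' @return list: `verdict` (`"pass"` or `"exclude"`), `reason`,
#'   `clean_frames`, `mean_fd_post`, and `ts` (the selected series, or
#'   `NULL` if excluded).
#' @export
qc_and_select <- function(ts, min_frames = 100, n_select = 100, fd = NULL) {
  .require_stage(ts, "trimmed", "qc_and_select")
  nclean <- n_frames(ts)
  kept <- attr(ts$data, "kept_frames") %||% seq_len(nclean)
  if (nclean < min_frames) {
    return(list(verdict = "exclude",
                reason = sprintf("only %d clean frames (< %d)",
                                 nclean, min_frames),
                clean_frames = nclean,
                mean_fd_post = NA_real_,
                ts = NULL))
  }
  sel <- seq_len(n_select)
  mean_fd_post <- if (is.null(fd)) NA_real_ else mean(fd[kept[sel]])
  ts$data <- ts$data[sel, , drop = FALSE]
  attr(ts$data, "kept_frames") <- NULL
  ts$frame_status <- ts$frame_status[sel]
  ts <- .advance_stage(ts, "selected")
  list(verdict = "pass", reason = NA_character_,
       clean_frames = nclean, mean_fd_post = mean_fd_post, ts = ts)
}

#' Run the full ordered denoising chain for one subject
#'
#' Convenience wrapper applying, in the fixed order: demean/detrend,
#' nuisance regression (global signal, tissue surrogates, Friston-24;
#' coefficients fit on frames with FD <= threshold), scrubbing with
#' interpolation, bandpass filtering, interpolated-frame removal, and
#' QC / clean-frame selection.
#'
#' @param ts a raw [bold_timeseries()].
#' @param motion frames x 6 motion parameters.
#' @param tissue_surrogates optional frames x k tissue signals.
#' @param fd_threshold scrubbing threshold, mm.
#' @param band band edges, Hz.
#' @param min_frames,n_select QC parameters (see [qc_and_select()]).
#' @param head_radius mm, for FD conversion.
#' @return the [qc_and_select()] result, augmented with `mean_fd_pre`
#'   (mean FD over all frames) and `pct_loss` (percentage of frames
#'   censored).
#' @export
denoise_subject <- function(ts, motion, tissue_surrogates = NULL,
                            fd_threshold = 0.3, band = c(0.009, 0.08),
                            min_frames = 100, n_select = 100,
                            head_radius = 50) {
  fd <- compute_fd(motion, head_radius = head_radius)
  censor <- fd > fd_threshold
  nuis <- build_nuisance(ts, motion, tissue_surrogates)
  out <- demean_detrend(ts)
  out <- regress_nuisance(out, nuis, censor_mask = censor)
  out <- censor_and_interpolate(out, fd, threshold = fd_threshold)
  out <- bandpass(out, band[1], band[2])
  out <- drop_interpolated(out)
  res <- qc_and_select(out, min_frames = min_frames, n_select = n_select,
                       fd = fd)
  res$mean_fd_pre <- mean(fd)
  res$pct_loss <- 100 * mean(censor)
  res
}
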