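# Half-bleach FRAP: normalization of bleached/unbleached hemisphere traces
# to a dimensionless recovery curve, single-exponential summary fits and
# replicate aggregation.
#
# Normalization convention: the per-time-point hemisphere ratio
# I_t = bleached(t) / unbleached(t) corrects for acquisition photofading;
# the recovery is FR(t) = (I_t - I_t0) / (I_pre - I_t0), where t0 is the
# first post-bleach time point and I_pre the mean pre-bleach ratio. FR is 0
# at t0 by construction and 1 when the ratio returns to its pre-bleach
# value.

#' Construct a half-bleach FRAP trace
#'
#' @param time Time points in seconds, strictly increasing.
#' @param bleached,unbleached Intensities of the bleached and unbleached
#'   droplet hemispheres (a.u.); `unbleached` must be positive throughout.
#' @param prebleach Logical vector flagging pre-bleach frames (at least one;
#'   all must precede the post-bleach frames).
#' @param id Trace identifier.
#' @return List of class `frap_trace`.
#' @export
frap_trace <- function(time, bleached, unbleached, prebleach, id = "trace") {
  stopifnot(length(time) == length(bleached),
            length(time) == length(unbleached),
            length(time) == length(prebleach))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing",
                                 call. = FALSE)
  if (any(unbleached <= 0)) stop("unbleached intensities must be positive",
                                 call. = FALSE)
  if (!any(prebleach) || !any(!prebleach)) {
    stop("trace needs both pre-bleach and post-bleach frames", call. = FALSE)
  }
  if (max(which(prebleach)) > min(which(!prebleach))) {
    stop("pre-bleach frames must precede post-bleach frames", call. = FALSE)
  }
  structure(list(id = id, time = as.numeric(time),
                 bleached = as.numeric(bleached),
                 unbleached = as.numeric(unbleached),
                 prebleach = as.logical(prebleach)),
            class = "frap_trace")
}

#' Read FRAP traces from CSV
#'
#' Expected columns: `time`, `bleached`, `unbleached`, `prebleach`
#' (logical/0-1) and optionally `id` for multi-trace files.
#'
#' @param path CSV file.
#' @return List of `frap_trace` objects.
#' @export
read_frap_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time", "bleached", "unbleached", "prebleach") %in%
                  names(d)))
  if (is.null(d$id)) d$id <- "trace"
  lapply(split(d, d$id), function(x) {
    frap_trace(x$time, x$bleached, x$unbleached, as.logical(x$prebleach),
               id = as.character(x$id[1]))
  })
}

#' Normalize a half-bleach trace to a recovery curve
#'
#' @param trace A [frap_trace()].
#' @return Data frame of class `recovery_curve` with `time` (seconds since
#'   the first post-bleach frame) and `fr` (dimensionless recovery, 0 at
#'   t0). Values outside `[-1.5, 1.5]` are kept but flagged via the
#'   `flagged` attribute. A trace where the pre-bleach ratio does not
#'   exceed the first post-bleach ratio is a degenerate bleach and errors.
#' @examples
#' t <- 0:19
#' tr <- frap_trace(t, c(100, 100, 50 + 50 * (1 - exp(-0.2 * (0:17)))),
#'                  rep(100, 20), c(TRUE, TRUE, rep(FALSE, 18)))
#' head(normalize_halfbleach(tr))
#' @export
normalize_halfbleach <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  ratio <- trace$bleached / trace$unbleached
  i_pre <- mean(ratio[trace$prebleach])
  post <- which(!trace$prebleach)
  i_t0 <- ratio[post[1]]
  if (i_pre <= i_t0) {
    stop("degenerate bleach: pre-bleach ratio does not exceed the first ",
         "post-bleach ratio", call. = FALSE)
  }
  fr <- (ratio[post] - i_t0) / (i_pre - i_t0)
  out <- data.frame(time = trace$time[post] - trace$time[post[1]], fr = fr)
  structure(out, class = c("recovery_curve", "data.frame"),
            id = trace$id, flagged = any(abs(fr) > 1.5))
}

#' Fit a single-exponential recovery model
#'
#' Least-squares fit of `FR(t) = A * (1 - exp(-k t))`, the standard
#' summary of condensate internal dynamics: `A` is the mobile fraction and
#' `ln(2)/k` the recovery half-time. Initialization uses the curve maximum
#' and the time at half-maximum; bounds are `A` in \[0, 1.2\] and `k > 0`.
#' Non-convergence is flagged, not thrown.
#'
#' @param curve A [normalize_halfbleach()] result (or data frame with
#'   `time`, `fr`); at least five post-bleach points.
#' @param solid_threshold Mobile fractions below this value flag the
#'   droplet as solid-like (default 0.1, i.e. less than 10 percent
#'   recovery).
#' @return List of class `recovery_fit`: `A`, `k`, `half_time`,
#'   `residual_rms`, `converged`, `solid_like`.
#' @export
fit_recovery <- function(curve, solid_threshold = 0.1) {
  t <- curve$time; y <- curve$fr
  if (length(t) < 5L) stop("need at least five post-bleach points",
                           call. = FALSE)
  a0 <- min(max(max(y), 1e-3), 1.2)
  t_half <- t[which(y >= a0 / 2)[1]]
  k0 <- if (is.na(t_half) || t_half <= 0) 1 / max(t[t > 0][1], 1e-6) else
    1 / t_half
  fit <- tryCatch(
    nls(y ~ A * (1 - exp(-k * t)), start = list(A = a0, k = k0),
        lower = c(A = 0, k = 1e-9), upper = c(A = 1.2, k = Inf),
        algorithm = "port",
        control = list(warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to a coarse grid + Nelder-Mead on (A, k)
    obj <- function(p) mean((y - p[1] * (1 - exp(-exp(p[2]) * t)))^2)
    op <- optim(c(a0, log(k0)), obj)
    A <- min(max(op$par[1], 0), 1.2); k <- exp(op$par[2])
    conv <- FALSE
  } else {
    A <- coef(fit)[["A"]]; k <- coef(fit)[["k"]]
    conv <- TRUE
  }
  res <- y - A * (1 - exp(-k * t))
  structure(list(A = A, k = k, half_time = log(2) / k,
                 residual_rms = sqrt(mean(res^2)), converged = conv,
                 solid_like = A < solid_threshold),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "<recovery_fit> A = %.3f, k = %.4g /s (t1/2 = %.3g s)%s%s\n",
    x$A, x$k, x$half_time,
    if (x$solid_like) ", solid-like" else "",
    if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' Aggregate replicate recovery curves
#'
#' Curves are linearly interpolated onto a common time grid and summarized
#' pointwise as mean and standard deviation, the representation used to
#' plot replicate half-bleach experiments.
#'
#' @param curves List of recovery curves (data frames with `time`, `fr`);
#'   at least two.
#' @param grid Time grid; defaults to the time points of the first curve
#'   restricted to the range covered by all curves.
#' @return Data frame with `time`, `mean`, `sd`, `n`.
#' @export
aggregate_replicates <- function(curves, grid = NULL) {
  if (length(curves) < 2L) stop("need at least two curves", call. = FALSE)
  lo <- max(vapply(curves, function(c_) min(c_$time), numeric(1)))
  hi <- min(vapply(curves, function(c_) max(c_$time), numeric(1)))
  if (lo > hi) stop("curves have disjoint time ranges", call. = FALSE)
  if (is.null(grid)) {
    grid <- curves[[1]]$time
    grid <- grid[grid >= lo & grid <= hi]
  } else if (any(grid < lo | grid > hi)) {
    stop("grid extends outside the common time range", call. = FALSE)
  }
  m <- vapply(curves, function(c_) approx(c_$time, c_$fr, xout = grid)$y,
              numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  data.frame(time = grid, mean = rowMeans(m), sd = apply(m, 1, sd),
             n = length(curves))
}
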