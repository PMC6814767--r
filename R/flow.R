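# Single-cell splicing analysis from three-colour flow cytometry:
# compensation, gating, per-cell mCherry/GFP ratio, expression-binned
# summaries and expression-window comparisons between variants.

FLUOR_CHANNELS <- c("BFP", "GFP", "mCherry")

#' Linear spillover compensation
#'
#' Observed fluorescence is modelled as `observed = true %*% M` with `M`
#' the spillover matrix (diagonal 1, `M[i, j]` the fraction of channel i
#' signal read in channel j); compensation right-multiplies by the inverse.
#' The identity matrix is a no-op.
#'
#' @param events Data frame with the fluorescence channels (BFP, GFP,
#'   mCherry) and any other columns (passed through untouched).
#' @param spillover Square matrix with dimnames over the fluorescence
#'   channels; must be invertible with unit diagonal.
#' @return `events` with compensated fluorescence channels.
#' @export
compensate <- function(events, spillover) {
  ch <- rownames(spillover)
  stopifnot(!is.null(ch), identical(ch, colnames(spillover)),
            all(ch %in% names(events)))
  if (any(abs(diag(spillover) - 1) > 1e-12)) {
    stop("spillover matrix must have a unit diagonal", call. = FALSE)
  }
  inv <- tryCatch(solve(spillover), error = function(e) {
    stop("spillover matrix is singular", call. = FALSE)
  })
  obs <- as.matrix(events[, ch, drop = FALSE])
  events[, ch] <- obs %*% inv
  events
}

#' Gating configuration
#'
#' @param fsc_min,ssc_min Debris gate: minimum forward/side scatter area.
#' @param singlet_tol Singlet gate: maximum relative deviation of
#'   `FSC_H / FSC_A` from the population median (doublets have roughly
#'   double area at a given height).
#' @param bfp_min BFP-positive threshold (expression gate).
#' @param gfp_floor Minimum GFP for the mCherry/GFP ratio to be defined;
#'   `NULL` means "use the 1st percentile of gated GFP-positive events".
#' @return Named list.
#' @export
gating_config <- function(fsc_min = 1e4, ssc_min = 5e3, singlet_tol = 0.15,
                          bfp_min = 1e3, gfp_floor = NULL) {
  list(fsc_min = fsc_min, ssc_min = ssc_min, singlet_tol = singlet_tol,
       bfp_min = bfp_min, gfp_floor = gfp_floor)
}

#' Sequential gating: debris, singlets, BFP-positive
#'
#' @param events Data frame with `FSC_A`, `FSC_H`, `SSC_A` and the
#'   fluorescence channels.
#' @param config See [gating_config()].
#' @return List of class `gate_result`: `events` (gated), `report` (data
#'   frame with per-gate input, kept and lost counts). Gating to zero
#'   events warns rather than errors.
#' @export
gate <- function(events, config = gating_config()) {
  report <- data.frame(gate = character(0), n_in = integer(0),
                       n_kept = integer(0), n_lost = integer(0))
  push <- function(name, n_in, n_kept) {
    rbind(report, data.frame(gate = name, n_in = n_in, n_kept = n_kept,
                             n_lost = n_in - n_kept))
  }
  n0 <- nrow(events)
  keep <- events$FSC_A >= config$fsc_min & events$SSC_A >= config$ssc_min
  events <- events[keep, , drop = FALSE]
  report <- push("debris", n0, nrow(events))

  n1 <- nrow(events)
  if (n1) {
    r <- events$FSC_H / events$FSC_A
    keep <- abs(r / median(r) - 1) <= config$singlet_tol
    events <- events[keep, , drop = FALSE]
  }
  report <- push("singlets", n1, nrow(events))

  n2 <- nrow(events)
  events <- events[events$BFP >= config$bfp_min, , drop = FALSE]
  report <- push("bfp_positive", n2, nrow(events))

  if (!nrow(events)) warning("no events left after gating")
  structure(list(events = events, report = report), class = "gate_result")
}

#' Per-cell splicing ratio mCherry/GFP
#'
#' The splicing reporter couples successful exon skipping to mCherry
#' production from a GFP-normalized transcript, so the per-cell
#' mCherry/GFP ratio reads out splicing efficiency. Events whose GFP falls
#' below the floor are excluded (ratio undefined) and counted.
#'
#' @param events Gated events (data frame or `gate_result`).
#' @param gfp_floor Minimum GFP; `NULL` uses the 1st percentile of positive
#'   GFP values.
#' @return Data frame of the retained events with an added `ratio` column;
#'   attribute `n_excluded` counts the below-floor events.
#' @export
splicing_ratio <- function(events, gfp_floor = NULL) {
  if (inherits(events, "gate_result")) events <- events$events
  if (is.null(gfp_floor)) {
    pos <- events$GFP[events$GFP > 0]
    gfp_floor <- if (length(pos)) as.numeric(quantile(pos, 0.01)) else 0
  }
  keep <- events$GFP > gfp_floor
  out <- events[keep, , drop = FALSE]
  out$ratio <- out$mCherry / out$GFP
  structure(out, n_excluded = sum(!keep), gfp_floor = gfp_floor)
}

#' Bin cells by expression and summarize splicing ratios
#'
#' Cells are binned into `n_bins` log-spaced BFP (expression) bins;
#' per-bin median ratio, interquartile range, count and a kernel density of
#' the ratio (violin data) are reported.
#'
#' @param events Data frame with `ratio` and `BFP` columns (from
#'   [splicing_ratio()]).
#' @param n_bins Number of log-spaced BFP bins (at least 2; use
#'   [window_compare()] for single-window summaries).
#' @return List of class `splicing_summary`: `bins` (data frame with
#'   `bin`, `bfp_lo`, `bfp_hi`, `n`, `median`, `iqr`) and `density` (list
#'   of per-bin `stats::density` results, `NULL` where n < 3).
#' @export
bin_and_summarize <- function(events, n_bins = 20L) {
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  if (!nrow(events)) stop("no events with a valid ratio", call. = FALSE)
  b <- events$BFP
  if (any(b <= 0)) stop("BFP must be positive for log binning",
                        call. = FALSE)
  edges <- exp(seq(log(min(b)), log(max(b)), length.out = n_bins + 1L))
  bin <- findInterval(b, edges, all.inside = TRUE)
  rows <- lapply(seq_len(n_bins), function(i) {
    r <- events$ratio[bin == i]
    data.frame(bin = i, bfp_lo = edges[i], bfp_hi = edges[i + 1L],
               n = length(r),
               median = if (length(r)) median(r) else NA_real_,
               iqr = if (length(r)) IQR(r) else NA_real_)
  })
  dens <- lapply(seq_len(n_bins), function(i) {
    r <- events$ratio[bin == i]
    if (length(r) >= 3L) density(r, bw = "SJ") else NULL
  })
  structure(list(bins = do.call(rbind, rows), density = dens),
            class = "splicing_summary")
}

#' Compare variants within a common expression window
#'
#' Restricts each variant to cells whose BFP (expression) lies inside the
#' window, then reports the per-variant median and IQR of the splicing
#' ratio, the rank ordering, and pairwise two-sided Wilcoxon rank-sum
#' p-values. Variants with no cell in the window are flagged and excluded.
#'
#' @param variants Named list of data frames with `ratio` and `BFP`
#'   columns (one per TDP43 variant).
#' @param window Length-2 numeric `c(lo, hi)` BFP window.
#' @return List of class `window_comparison`: `table` (data frame with
#'   `variant`, `n`, `median`, `iqr`, ordered as supplied), `ranking`
#'   (variant names by decreasing median), `pairwise` (matrix of Wilcoxon
#'   p-values) and `excluded` (variants with empty windows).
#' @export
window_compare <- function(variants, window) {
  stopifnot(length(window) == 2L, window[1] < window[2],
            !is.null(names(variants)))
  sel <- lapply(variants, function(v) {
    v$ratio[v$BFP >= window[1] & v$BFP <= window[2]]
  })
  excluded <- names(sel)[vapply(sel, length, integer(1)) == 0L]
  sel <- sel[setdiff(names(sel), excluded)]
  if (!length(sel)) stop("window is empty for every variant", call. = FALSE)
  tab <- data.frame(variant = names(sel),
                    n = vapply(sel, length, integer(1)),
                    median = vapply(sel, median, numeric(1)),
                    iqr = vapply(sel, IQR, numeric(1)),
                    row.names = NULL)
  nv <- length(sel)
  pw <- matrix(NA_real_, nv, nv, dimnames = list(names(sel), names(sel)))
  if (nv > 1L) {
    for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
      p <- suppressWarnings(wilcox.test(sel[[i]], sel[[j]])$p.value)
      pw[i, j] <- pw[j, i] <- p
    }
  }
  structure(list(table = tab,
                 ranking = tab$variant[order(-tab$median)],
                 pairwise = pw, excluded = excluded),
            class = "window_comparison")
}

#' @export
print.window_comparison <- function(x, ...) {
  cat("<window_comparison>\n")
  print(x$table, row.names = FALSE)
  if (length(x$excluded)) {
    cat("excluded (empty window):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
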