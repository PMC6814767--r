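# Sliding-window hydropathy profiles and hydrophobic ("sticker") clusters.
#
# All scales are stored oriented so that LARGER values mean MORE hydrophobic
# (hydrophilicity scales from the literature are sign-flipped on entry) and
# are min-max rescaled over the 20 residue values to [0, 1] before use.

.scale_registry <- local({
  s <- list(
    FaucherePliska = c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
                       Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
                       L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
                       S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22),
    KyteDoolittle = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                      L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
    HoppWoods = -c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
                   Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8,
                   L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
                   S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
    Eisenberg = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                  Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                  L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                  S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
    Cornette = c(A = 0.2, R = 1.4, N = -0.5, D = -3.1, C = 4.1,
                 Q = -2.8, E = -1.8, G = 0.0, H = 0.5, I = 4.8,
                 L = 5.7, K = -3.1, M = 4.2, F = 4.4, P = -2.2,
                 S = -0.5, T = -1.9, W = 1.0, Y = 3.2, V = 4.7),
    Rose = c(A = 0.74, R = 0.64, N = 0.63, D = 0.62, C = 0.91,
             Q = 0.62, E = 0.62, G = 0.72, H = 0.78, I = 0.88,
             L = 0.85, K = 0.52, M = 0.85, F = 0.88, P = 0.64,
             S = 0.66, T = 0.70, W = 0.85, Y = 0.76, V = 0.86),
    Janin = c(A = 0.3, R = -1.4, N = -0.5, D = -0.6, C = 0.9,
              Q = -0.7, E = -0.7, G = 0.3, H = -0.1, I = 0.7,
              L = 0.5, K = -1.8, M = 0.4, F = 0.5, P = -0.3,
              S = -0.1, T = -0.2, W = 0.3, Y = -0.4, V = 0.6),
    EngelmanGES = c(A = 1.6, R = -12.3, N = -4.8, D = -9.2, C = 2.0,
                    Q = -4.1, E = -8.2, G = 1.0, H = -3.0, I = 3.1,
                    L = 2.8, K = -8.8, M = 3.4, F = 3.7, P = -0.2,
                    S = 0.6, T = 1.2, W = 1.9, Y = -0.7, V = 2.6),
    Chothia = c(A = 0.38, R = 0.01, N = 0.12, D = 0.15, C = 0.45,
                Q = 0.07, E = 0.18, G = 0.36, H = 0.17, I = 0.60,
                L = 0.45, K = 0.03, M = 0.40, F = 0.50, P = 0.18,
                S = 0.22, T = 0.23, W = 0.27, Y = 0.15, V = 0.54),
    BlackMould = c(A = 0.616, R = 0.000, N = 0.236, D = 0.028, C = 0.680,
                   Q = 0.251, E = 0.043, G = 0.501, H = 0.165, I = 0.943,
                   L = 0.943, K = 0.283, M = 0.738, F = 1.000, P = 0.711,
                   S = 0.359, T = 0.450, W = 0.878, Y = 0.880, V = 0.825),
    BullBreese = -c(A = 0.61, R = 0.69, N = 0.89, D = 0.61, C = 0.36,
                    Q = 0.97, E = 0.51, G = 0.81, H = 0.69, I = -1.45,
                    L = -1.65, K = 0.46, M = -0.66, F = -1.52, P = -0.17,
                    S = 0.42, T = 0.29, W = -1.20, Y = -1.43, V = -0.75),
    Guy = -c(A = 0.10, R = 1.91, N = 0.48, D = 0.78, C = -1.42,
             Q = 0.95, E = 0.83, G = 0.33, H = -0.50, I = -1.13,
             L = -1.18, K = 1.40, M = -1.59, F = -2.12, P = 0.73,
             S = 0.52, T = 0.07, W = -0.51, Y = -0.21, V = -1.27),
    MiyazawaJernigan = c(A = 5.33, R = 4.18, N = 3.71, D = 3.59, C = 7.93,
                         Q = 3.87, E = 3.65, G = 4.48, H = 5.10, I = 8.83,
                         L = 8.47, K = 2.95, M = 8.95, F = 9.03, P = 3.87,
                         S = 4.09, T = 4.49, W = 7.66, Y = 5.89, V = 7.63),
    Roseman = c(A = 0.39, R = -3.95, N = -1.91, D = -3.81, C = 0.25,
                Q = -1.30, E = -2.91, G = 0.00, H = -0.64, I = 1.82,
                L = 1.82, K = -2.77, M = 0.96, F = 2.27, P = 0.99,
                S = -1.24, T = -1.00, W = 2.13, Y = 1.47, V = 1.30),
    WimleyWhite = c(A = -0.17, R = -0.81, N = -0.42, D = -1.23, C = 0.24,
                    Q = -0.58, E = -2.02, G = -0.01, H = -0.17, I = 0.31,
                    L = 0.56, K = -0.99, M = 0.23, F = 1.13, P = -0.45,
                    S = -0.13, T = -0.14, W = 1.85, Y = 0.94, V = -0.07)
  )
  lapply(s, function(x) x[AA20])
})

#' Registered hydrophobicity scales
#'
#' Fifteen residue-level hydrophobicity scales from the standard literature
#' compilations, all oriented so that larger means more hydrophobic.
#' `FaucherePliska` is the default scale used throughout the package.
#'
#' @return Character vector of scale names.
#' @export
hydrophobicity_scales <- function() names(.scale_registry)

#' Per-residue values of a hydrophobicity scale
#'
#' @param scale Scale name (see [hydrophobicity_scales()]) or a named numeric
#'   vector giving a value for each of the 20 residues.
#' @param rescaled If `TRUE` (default) min-max rescale the 20 values to
#'   span exactly \[0, 1\].
#' @return Named numeric vector over the 20 canonical residues.
#' @examples
#' scale_values("FaucherePliska")[["W"]]  # 1: the most hydrophobic residue
#' @export
scale_values <- function(scale = "FaucherePliska", rescaled = TRUE) {
  if (is.character(scale)) {
    if (!scale %in% names(.scale_registry)) {
      stop("unknown scale '", scale, "'; see hydrophobicity_scales()",
           call. = FALSE)
    }
    v <- .scale_registry[[scale]]
  } else {
    if (!all(AA20 %in% names(scale))) {
      stop("custom scale must name all 20 residues", call. = FALSE)
    }
    v <- as.numeric(scale[AA20])
    names(v) <- AA20
  }
  if (rescaled) v <- (v - min(v)) / (max(v) - min(v))
  v
}

#' Sliding-window hydropathy profile
#'
#' Mean rescaled hydrophobicity in a centered sliding window of `window`
#' residues (default 5). No edge padding is used: values exist only where
#' the full window fits, so the profile is `window - 1` positions shorter
#' than the sequence. Window centers are reported in full-length
#' coordinates.
#'
#' @param record A [protein_record()].
#' @param scale Scale name or named numeric vector, see [scale_values()].
#' @param window Odd window size in residues; sequence must be at least this
#'   long.
#' @return Data frame of class `hydropathy_profile` with columns `position`
#'   (window center, full-length) and `value` (in \[0, 1\]); attributes
#'   `record`, `scale` and `window`.
#' @examples
#' hp <- hydropathy_profile(tdp43_ctd())
#' range(hp$value)
#' @export
hydropathy_profile <- function(record, scale = "FaucherePliska",
                               window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  ch <- record_residues(record)
  if (length(ch) < window) {
    stop(sprintf("sequence '%s' (%d aa) shorter than window (%d)",
                 record$id, length(ch), window), call. = FALSE)
  }
  v <- scale_values(scale, rescaled = TRUE)[ch]
  cs <- cumsum(c(0, v))
  n <- length(ch) - window + 1L
  vals <- (cs[(window + 1L):(length(ch) + 1L)] - cs[1:n]) / window
  centers <- record_positions(record)[seq_len(n) + (window - 1L) %/% 2L]
  structure(data.frame(position = centers, value = as.numeric(vals)),
            class = c("hydropathy_profile", "data.frame"),
            record = record,
            scale = if (is.character(scale)) scale else "custom",
            window = window)
}

# Topographic prominence of a local maximum: walk each side to the nearest
# strictly higher value (or the profile boundary), tracking the minimum seen;
# the key saddle is the higher of the two side minima.
.peak_prominence <- function(v, i) {
  h <- v[i]
  n <- length(v)
  bases <- numeric(0)
  for (dir in c(-1L, 1L)) {
    j <- i + dir
    if (j < 1L || j > n) next
    m <- h
    while (j >= 1L && j <= n && v[j] <= h) {
      m <- min(m, v[j])
      j <- j + dir
    }
    bases <- c(bases, m)
  }
  if (!length(bases)) return(0)
  h - max(bases)
}

#' Detect hydrophobic clusters in a hydropathy profile
#'
#' Local maxima of the profile are candidate "stickers"; candidates must
#' have topographic prominence of at least `prominence_min` (on the 0-1
#' scale) and are thinned greedily (most prominent first) so that accepted
#' peaks are at least `min_separation` residues apart. Maxima at the profile
#' boundaries are eligible, because the profile stops at the last full
#' window while terminal stickers (such as the C-terminal tryptophan motif
#' of TDP43) are real. Plateau maxima are reported at their most N-terminal
#' position. The shipped defaults are calibrated such that the packaged
#' human CTD yields four clusters in each IDR.
#'
#' @param profile A [hydropathy_profile()].
#' @param prominence_min Minimum prominence (default 0.125).
#' @param min_separation Minimum center-to-center distance in residues
#'   (default 5).
#' @param regions Optional named list of `c(start, end)` intervals; if
#'   given, only peaks whose center falls inside one of them are returned
#'   and labelled with the region name.
#' @param reach Residue radius around a peak center within which hydrophobic
#'   residues are assigned to the cluster interval (default
#'   `min_separation`).
#' @param scheme [residue_classes()] used for the cluster intervals.
#' @return Data frame with columns `center`, `height`, `prominence`,
#'   `start`, `end`, `region` (`NA` when `regions` is `NULL`), ordered by
#'   `center`. Zero rows when nothing passes the filters.
#' @examples
#' hp <- hydropathy_profile(tdp43_ctd())
#' dom <- domain_partition()
#' nrow(detect_clusters(hp, regions = dom[c("IDR1", "IDR2")]))  # 8
#' @export
detect_clusters <- function(profile, prominence_min = 0.125,
                            min_separation = 5L, regions = NULL,
                            reach = min_separation,
                            scheme = residue_classes()) {
  v <- profile$value
  p <- profile$position
  n <- length(v)
  empty <- data.frame(center = integer(0), height = numeric(0),
                      prominence = numeric(0), start = integer(0),
                      end = integer(0), region = character(0))
  if (n == 0L) return(empty)
  # collapse plateaus: runs of equal value act as one candidate anchored at
  # their N-terminal end
  r <- rle(v)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  rv <- r$values
  k <- length(rv)
  is_max <- vapply(seq_len(k), function(i) {
    left <- if (i > 1L) rv[i - 1L] else -Inf
    right <- if (i < k) rv[i + 1L] else -Inf
    rv[i] > left && rv[i] > right
  }, logical(1))
  if (k == 1L) is_max <- FALSE  # constant profile: no cluster
  cand <- run_start[is_max]
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) .peak_prominence(v, i), numeric(1))
  keep <- prom >= prominence_min
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) return(empty)
  # region filter comes before separation thinning: peaks outside the
  # regions of interest (e.g. inside the conserved helical region) must not
  # suppress nearby in-region stickers
  centers <- p[cand]
  region <- rep(NA_character_, length(cand))
  if (!is.null(regions)) {
    hit <- rep(FALSE, length(cand))
    for (nm in names(regions)) {
      iv <- regions[[nm]]
      inside <- centers >= iv[1] & centers <= iv[2]
      region[inside] <- nm
      hit <- hit | inside
    }
    cand <- cand[hit]; prom <- prom[hit]
    centers <- centers[hit]; region <- region[hit]
  }
  if (!length(cand)) return(empty)
  # greedy separation: most prominent first, ties toward the N-terminus
  ord <- order(-prom, -v[cand], p[cand])
  acc <- integer(0)
  for (i in ord) {
    if (!length(acc) || all(abs(p[cand[acc]] - p[cand[i]]) >= min_separation)) {
      acc <- c(acc, i)
    }
  }
  acc <- sort(acc)
  cand <- cand[acc]
  prom <- prom[acc]
  centers <- centers[acc]
  region <- region[acc]
  rec <- attr(profile, "record")
  starts <- centers
  ends <- centers
  if (!is.null(rec)) {
    pos <- record_positions(rec)
    phi <- pos[record_residues(rec) %in% scheme$hydrophobic]
    for (i in seq_along(centers)) {
      near <- phi[abs(phi - centers[i]) <= reach]
      if (length(near)) { starts[i] <- min(near); ends[i] <- max(near) }
    }
  }
  out <- data.frame(center = centers, height = v[cand], prominence = prom,
                    start = starts, end = ends, region = region)
  out[order(out$center), , drop = FALSE]
}

#' Hydrophobic clusters of a CTD-like record, per IDR
#'
#' Convenience wrapper: computes the hydropathy profile of `record` and
#' detects clusters restricted to the IDR1 and IDR2 intervals of
#' `boundaries` (the conserved region is a separate entity and is not
#' counted as an IDR sticker).
#'
#' @param record A [protein_record()]; defaults to the packaged human CTD.
#' @param boundaries A [domain_partition()].
#' @param ... Passed to [hydropathy_profile()] and [detect_clusters()]
#'   (`scale`, `window`, `prominence_min`, `min_separation`, ...).
#' @return As [detect_clusters()], with `region` in `{"IDR1", "IDR2"}`.
#' @export
ctd_clusters <- function(record = tdp43_ctd(),
                         boundaries = domain_partition(), ...) {
  dots <- list(...)
  prof_args <- dots[names(dots) %in% c("scale", "window")]
  det_args <- dots[names(dots) %in%
                     c("prominence_min", "min_separation", "reach", "scheme")]
  prof <- do.call(hydropathy_profile, c(list(record), prof_args))
  do.call(detect_clusters,
          c(list(prof, regions = boundaries[c("IDR1", "IDR2")]), det_args))
}

#' Spacing statistics of detected clusters
#'
#' @param clusters Data frame from [detect_clusters()] (or a numeric vector
#'   of peak positions).
#' @return List with `spacings` (distances between consecutive peak
#'   centers), `mean` and `sd`. Fewer than two clusters gives empty spacings
#'   with a warning.
#' @export
cluster_spacing <- function(clusters) {
  centers <- if (is.data.frame(clusters)) clusters$center else
    as.numeric(clusters)
  centers <- sort(centers)
  if (length(centers) < 2L) {
    warning("fewer than two clusters: no spacings")
    return(list(spacings = numeric(0), mean = NA_real_, sd = NA_real_))
  }
  sp <- diff(centers)
  list(spacings = sp, mean = mean(sp), sd = sd(sp))
}

#' Positional conservation of clusters across a collection
#'
#' For each sequence of an aligned-layout collection (all records sharing
#' one coordinate system, as homolog ensembles generated by
#' [gen_homologs()] do), clusters are detected and each position is scored
#' with the fraction of sequences that have a peak center within
#' `tolerance` residues of it.
#'
#' @param records List of [protein_record()] objects on a common coordinate
#'   system (at least two).
#' @param tolerance Residue tolerance for matching a peak to a position
#'   (default 5, half-window scale positional jitter).
#' @param anchors Optional positions of interest; if given, a per-anchor
#'   recovery frequency is also returned.
#' @param regions Regions scanned for peaks (default: the IDR intervals of
#'   the shipped domain partition, so conserved-region peaks are ignored).
#' @param prominence_min Prominence threshold for the ensemble scan. The
#'   default (0.08) is deliberately more permissive than the single-
#'   sequence cluster call: sequence divergence erodes saddle depth around
#'   a sticker long before it erodes the sticker itself, and the scan asks
#'   "is there a hydrophobic elevation here", not "is this a major
#'   cluster".
#' @param ... Passed to [hydropathy_profile()] / [detect_clusters()]
#'   (`scale`, `window`, `min_separation`).
#' @return List with `position`, `frequency` (per-position peak frequency)
#'   and, when `anchors` is given, `anchor_frequency` (named by anchor).
#' @export
cluster_conservation <- function(records, tolerance = 5L, anchors = NULL,
                                 regions = domain_partition()[c("IDR1",
                                                                "IDR2")],
                                 prominence_min = 0.08, ...) {
  if (length(records) < 2L) stop("need at least two records", call. = FALSE)
  dots <- list(...)
  prof_args <- dots[names(dots) %in% c("scale", "window")]
  det_args <- dots[names(dots) %in% c("min_separation", "reach", "scheme")]
  det_args$prominence_min <- prominence_min
  det_args$regions <- regions
  peaks <- lapply(records, function(r) {
    prof <- do.call(hydropathy_profile, c(list(r), prof_args))
    do.call(detect_clusters, c(list(prof), det_args))$center
  })
  pos_range <- range(unlist(lapply(records, record_positions)))
  position <- seq.int(pos_range[1], pos_range[2])
  freq <- vapply(position, function(p) {
    mean(vapply(peaks, function(ctr) any(abs(ctr - p) <= tolerance),
                logical(1)))
  }, numeric(1))
  out <- list(position = position, frequency = freq)
  if (!is.null(anchors)) {
    out$anchor_frequency <- setNames(
      freq[match(as.integer(anchors), position)], anchors)
  }
  out
}
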