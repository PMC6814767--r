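# Condensate quantification: nuclear segmentation, droplet detection,
# condensed/diffuse classification, saturation-concentration estimation,
# concentration calibration and phase-onset analysis.

#' Parameters for nuclear segmentation
#'
#' @param threshold `"otsu"` (default) or a numeric intensity threshold.
#' @param min_area,max_area Accepted nucleus area range in pixels.
#' @param fill Fill holes inside nuclei before labelling.
#' @param split Split touching nuclei using distance-transform markers.
#' @param min_marker_distance Minimum marker separation (pixels).
#' @param min_marker_radius Minimum distance-transform value for a marker;
#'   suppresses spurious markers from boundary roughness.
#' @return Named list of parameters.
#' @export
nucleus_params <- function(threshold = "otsu", min_area = 50L,
                           max_area = Inf, fill = TRUE, split = TRUE,
                           min_marker_distance = 8, min_marker_radius = 4) {
  list(threshold = threshold, min_area = min_area, max_area = max_area,
       fill = fill, split = split,
       min_marker_distance = min_marker_distance,
       min_marker_radius = min_marker_radius)
}

#' Segment nuclei from a nuclear-stain image
#'
#' Global threshold (Otsu by default), hole filling, connected components,
#' marker-based splitting of touching nuclei (local maxima of the chamfer
#' distance transform as markers, pixels assigned to the nearest marker) and
#' an area filter. An image with no foreground yields an empty mask, not an
#' error.
#'
#' @param img Numeric matrix (nuclear-stain channel).
#' @param params See [nucleus_params()].
#' @return List of class `nucleus_mask`: `labels` (integer matrix, 0 =
#'   background) and `table` (data frame with `label`, `area`, `row`,
#'   `col` centroids).
#' @export
segment_nuclei <- function(img, params = nucleus_params()) {
  stopifnot(is.matrix(img))
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(img) else
    as.numeric(params$threshold)
  mask <- img > thr
  if (params$fill && any(mask)) mask <- fill_holes(mask)
  lab <- label_components(mask)
  if (params$split && max(lab) > 0L) {
    dt <- distance_transform(mask)
    out <- matrix(0L, nrow(img), ncol(img))
    nxt <- 0L
    for (l in seq_len(max(lab))) {
      pix <- which(lab == l)
      comp <- lab == l
      mk <- .local_maxima(dt, comp, min_value = params$min_marker_radius,
                          min_sep = params$min_marker_distance)
      if (nrow(mk) <= 1L) {
        nxt <- nxt + 1L
        out[pix] <- nxt
      } else {
        rr <- (pix - 1L) %% nrow(img) + 1L
        cc <- (pix - 1L) %/% nrow(img) + 1L
        d2 <- outer(rr, mk[, "row"], "-")^2 + outer(cc, mk[, "col"], "-")^2
        assign_ <- max.col(-d2, ties.method = "first")
        for (m in seq_len(nrow(mk))) {
          nxt <- nxt + 1L
          out[pix[assign_ == m]] <- nxt
        }
      }
    }
    lab <- out
  }
  # area filter, then renumber compactly
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    drop_ <- which(areas < params$min_area | areas > params$max_area)
    lab[lab %in% drop_] <- 0L
    old <- sort(unique(lab[lab > 0L]))
    lab[] <- match(lab, old, nomatch = 0L)
  }
  tab <- if (max(lab) > 0L) {
    idx <- which(lab > 0L)
    data.frame(label = sort(unique(lab[idx])),
               area = as.integer(tabulate(lab[idx])[sort(unique(lab[idx]))]),
               row = as.numeric(tapply((idx - 1L) %% nrow(lab) + 1L, lab[idx], mean)),
               col = as.numeric(tapply((idx - 1L) %/% nrow(lab) + 1L, lab[idx], mean)))
  } else {
    data.frame(label = integer(0), area = integer(0), row = numeric(0),
               col = numeric(0))
  }
  structure(list(labels = lab, table = tab), class = "nucleus_mask")
}

#' Mean reporter intensity per nucleus
#'
#' @param mask A `nucleus_mask` (or plain integer label matrix).
#' @param img Reporter-channel matrix of the same shape.
#' @return Data frame with `nucleus` and `intensity` (mean within mask).
#' @export
quantify_nuclei <- function(mask, img) {
  lab <- if (inherits(mask, "nucleus_mask")) mask$labels else mask
  if (!all(dim(lab) == dim(img))) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  if (max(lab) == 0L) {
    return(data.frame(nucleus = integer(0), intensity = numeric(0)))
  }
  idx <- which(lab > 0L)
  means <- tapply(img[idx], lab[idx], mean)
  data.frame(nucleus = as.integer(names(means)),
             intensity = as.numeric(means))
}

#' Parameters for droplet detection
#'
#' @param k_mad Detection threshold in robust SD units above the nuclear
#'   median intensity.
#' @param min_area,max_area Accepted droplet area in pixels.
#' @param circularity_min Minimum circularity. Circularity compares the
#'   object's area with that of a disk of equal radius of gyration
#'   (`area / (2 pi (m2 + 1/6))` with `m2` the mean squared centroid
#'   distance and `1/6` the per-pixel extent correction): 1 for disks,
#'   about 0.8 for a 2:1 ellipse and below 0.3 for thin streaks.
#' @return Named list of parameters.
#' @export
droplet_params <- function(k_mad = 3, min_area = 4L, max_area = 400L,
                           circularity_min = 0.7) {
  list(k_mad = k_mad, min_area = min_area, max_area = max_area,
       circularity_min = circularity_min)
}

#' Detect droplets (condensates) within segmented nuclei
#'
#' Within each nucleus, pixels brighter than the nuclear median plus
#' `k_mad` robust SDs are candidate dense-phase pixels; connected candidate
#' regions passing the area and circularity filters are reported as
#' droplets. A uniform nucleus yields no droplets.
#'
#' @param img Reporter-channel matrix.
#' @param mask A `nucleus_mask` or label matrix.
#' @param params See [droplet_params()].
#' @return Data frame with one row per droplet: `nucleus`, `row`, `col`
#'   (centroid), `area`, `circularity`, `mean_intensity`.
#' @export
detect_droplets <- function(img, mask, params = droplet_params()) {
  lab <- if (inherits(mask, "nucleus_mask")) mask$labels else mask
  if (!all(dim(lab) == dim(img))) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  out <- list()
  nr <- nrow(img)
  for (l in seq_len(max(lab))) {
    pix <- which(lab == l)
    if (!length(pix)) next
    vals <- img[pix]
    # robust noise scale from the upper quartile only: the lower tail of
    # camera counts is often clipped at zero in dim nuclei
    scale_ <- (quantile(vals, 0.75, names = FALSE) - median(vals)) / 0.6745
    thr <- median(vals) + params$k_mad * scale_
    cand <- matrix(FALSE, nr, ncol(img))
    cand[pix[vals > thr]] <- TRUE
    if (!any(cand)) next
    dl <- label_components(cand)
    for (d in seq_len(max(dl))) {
      dp <- which(dl == d)
      area <- length(dp)
      if (area < params$min_area || area > params$max_area) next
      rr <- (dp - 1L) %% nr + 1L
      cc <- (dp - 1L) %/% nr + 1L
      r0 <- mean(rr); c0 <- mean(cc)
      m2 <- mean((rr - r0)^2 + (cc - c0)^2)
      circ <- min(1, area / (2 * pi * (m2 + 1 / 6)))
      if (circ < params$circularity_min) next
      out[[length(out) + 1L]] <- data.frame(
        nucleus = l, row = r0, col = c0, area = area,
        circularity = circ, mean_intensity = mean(img[dp]))
    }
  }
  if (!length(out)) {
    return(data.frame(nucleus = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      circularity = numeric(0), mean_intensity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Quantify a two-channel field end to end
#'
#' Convenience pipeline: project both stacks, segment nuclei on the nuclear
#' channel, measure nuclear reporter intensity and detect droplets.
#'
#' @param nuclear,reporter Matrices or z-stacks (see [project_stack()]).
#' @param np,dp Parameter lists from [nucleus_params()] / [droplet_params()].
#' @return List with `mask`, `records` (data frame `nucleus`, `intensity`,
#'   `n_droplets`) and `droplets`.
#' @export
quantify_field <- function(nuclear, reporter, np = nucleus_params(),
                           dp = droplet_params()) {
  nuc <- project_stack(nuclear)
  rep_ <- project_stack(reporter)
  mask <- segment_nuclei(nuc, np)
  rec <- quantify_nuclei(mask, rep_)
  dr <- detect_droplets(rep_, mask, dp)
  rec$n_droplets <- as.integer(tabulate(dr$nucleus, nbins = max(c(rec$nucleus, 0L))))[rec$nucleus]
  list(mask = mask, records = rec, droplets = dr)
}

#' Classify nuclei as condensed, diffuse or untransfected
#'
#' Nuclei whose reporter intensity does not exceed the `q`-quantile of a
#' non-transfected control population are labelled `Untransfected` and
#' excluded from downstream statistics; the remainder are `Cond` if they
#' carry at least one accepted droplet, else `Diff`.
#'
#' @param records Data frame with `intensity` and `n_droplets`.
#' @param control Numeric vector of nuclear intensities from a
#'   non-transfected control population (non-empty).
#' @param q Control quantile for the untransfected cutoff (default 0.99).
#' @return `records` with a `class` column, plus attribute `summary`: a list
#'   with `cutoff`, `n_cond`, `n_diff`, `n_untransfected`, `pct_cond`,
#'   `pct_diff` (percentages over transfected cells).
#' @export
classify_and_filter <- function(records, control, q = 0.99) {
  if (!length(control)) stop("control distribution is empty", call. = FALSE)
  cutoff <- as.numeric(quantile(control, q))
  cls <- ifelse(records$intensity <= cutoff, "Untransfected",
                ifelse(records$n_droplets > 0L, "Cond", "Diff"))
  records$class <- cls
  n_cond <- sum(cls == "Cond"); n_diff <- sum(cls == "Diff")
  n_tr <- n_cond + n_diff
  attr(records, "summary") <- list(
    cutoff = cutoff, n_cond = n_cond, n_diff = n_diff,
    n_untransfected = sum(cls == "Untransfected"),
    pct_cond = if (n_tr) 100 * n_cond / n_tr else NA_real_,
    pct_diff = if (n_tr) 100 * n_diff / n_tr else NA_real_)
  records
}

#' Estimate the saturation concentration from classified nuclei
#'
#' Fits a logistic regression of condensate presence on nuclear reporter
#' intensity over transfected cells and reports the intensity at which the
#' probability of condensation is 0.5 -- the apparent saturation
#' concentration C_sat. Also reports the fraction of diffuse cells whose
#' nuclear level nevertheless exceeds the estimate, the statistic used to
#' argue that a variant fails to phase-separate above threshold.
#'
#' @param records Classified records from [classify_and_filter()] (rows with
#'   class `Untransfected` are dropped) or any data frame with `intensity`
#'   and `class` in `{"Cond", "Diff"}`.
#' @param n_min Minimum number of transfected cells (default 100).
#' @return List of class `csat_estimate`: `csat`, `slope`, `intercept`,
#'   `degenerate` (TRUE when only one class is present or the estimate falls
#'   outside the observed intensity range), `pct_diff_above` and `n`.
#' @export
estimate_csat <- function(records, n_min = 100L) {
  rec <- records[records$class %in% c("Cond", "Diff"), , drop = FALSE]
  if (nrow(rec) < n_min) {
    stop(sprintf("need at least %d classified transfected cells (have %d)",
                 n_min, nrow(rec)), call. = FALSE)
  }
  y <- as.integer(rec$class == "Cond")
  if (length(unique(y)) < 2L) {
    return(structure(list(csat = NA_real_, slope = NA_real_,
                          intercept = NA_real_, degenerate = TRUE,
                          pct_diff_above = NA_real_, n = nrow(rec)),
                     class = "csat_estimate"))
  }
  fit <- suppressWarnings(glm(y ~ rec$intensity, family = binomial()))
  b <- coef(fit)
  csat <- -b[[1]] / b[[2]]
  rng <- range(rec$intensity)
  degenerate <- !is.finite(csat) || b[[2]] <= 0 ||
    csat < rng[1] || csat > rng[2]
  diff_i <- rec$intensity[rec$class == "Diff"]
  structure(list(csat = as.numeric(csat), slope = as.numeric(b[[2]]),
                 intercept = as.numeric(b[[1]]), degenerate = degenerate,
                 pct_diff_above = 100 * mean(diff_i > csat),
                 n = nrow(rec)),
            class = "csat_estimate")
}

#' @export
print.csat_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat("<csat_estimate> degenerate (single class or out-of-range fit)\n")
  } else {
    cat(sprintf("<csat_estimate> C_sat = %.3g (n = %d; %.1f%% of diffuse cells above)\n",
                x$csat, x$n, x$pct_diff_above))
  }
  invisible(x)
}

#' Calibrate fluorescence intensity against known concentrations
#'
#' Least-squares affine fit of mean intensity against a titration series
#' (for GFP: 1, 2, 5 and 10 uM standards), used to convert nuclear
#' intensities into micromolar concentrations.
#'
#' @param standards Data frame with `concentration` (uM) and `intensity`
#'   (a.u.); at least two distinct concentrations.
#' @return List of class `calibration_curve` with `slope`, `intercept` and
#'   the fitted `model`.
#' @export
calibrate_concentration <- function(standards) {
  stopifnot(all(c("concentration", "intensity") %in% names(standards)))
  if (length(unique(standards$concentration)) < 2L) {
    stop("need at least two distinct standard concentrations", call. = FALSE)
  }
  if (length(unique(standards$intensity)) < 2L) {
    stop("standard intensities are identical: cannot fit", call. = FALSE)
  }
  fit <- lm(intensity ~ concentration, data = standards)
  slope <- coef(fit)[["concentration"]]
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  structure(list(slope = slope, intercept = coef(fit)[["(Intercept)"]],
                 model = fit),
            class = "calibration_curve")
}

#' Convert intensities to concentrations using a calibration curve
#'
#' @param cal A [calibrate_concentration()] fit.
#' @param intensity Numeric vector of intensities (a.u.).
#' @return Concentrations in uM; values that invert to below zero are
#'   clipped to 0 with a warning.
#' @export
convert_to_concentration <- function(cal, intensity) {
  conc <- (intensity - cal$intercept) / cal$slope
  if (any(conc < 0)) {
    warning(sum(conc < 0), " converted value(s) below zero clipped to 0")
    conc[conc < 0] <- 0
  }
  conc
}

#' Phase-separation onset in a per-cell focus-count time series
#'
#' The onset is the first frame at which at least one accepted focus is
#' present and persists for `k` consecutive frames (persistence suppresses
#' single-frame noise); the initial focus count is read at the onset frame.
#'
#' @param counts Integer vector of per-frame focus counts for one cell.
#' @param frames Frame identifiers; defaults to `seq_along(counts) - 1`
#'   (0-based movie frames).
#' @param k Persistence in frames (default 2).
#' @return List with `onset` (frame id or `NA` if never) and
#'   `initial_foci` (count at onset, `NA` if never).
#' @export
detect_onset <- function(counts, frames = seq_along(counts) - 1L, k = 2L) {
  stopifnot(length(counts) == length(frames))
  run <- 0L
  for (i in seq_along(counts)) {
    run <- if (counts[i] >= 1L) run + 1L else 0L
    if (run >= k) {
      start <- i - k + 1L
      return(list(onset = frames[start], initial_foci = counts[start]))
    }
  }
  list(onset = NA, initial_foci = NA_integer_)
}

#' Compare onset times or focus counts between two groups
#'
#' Two-sided unpaired Student t-test; cells without onset (`NA`) are
#' excluded and their number reported.
#'
#' @param a,b Numeric vectors (onset frames or initial focus counts).
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_excluded`.
#' @export
compare_groups <- function(a, b) {
  n_ex <- sum(is.na(a)) + sum(is.na(b))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       n_excluded = n_ex)
}
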