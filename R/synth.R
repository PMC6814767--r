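# Seeded synthetic-data generators. Each generator states an explicit
# statistical world (defaults follow the experimental regimes the pipeline
# is designed for), returns the generated data together with the full
# ground truth needed to score recovery, and is byte-deterministic given
# (seed, parameters).

#' Generate a homolog ensemble with conserved hydrophobic anchors
#'
#' Starting from a template CTD-like record (default: the packaged human
#' CTD), hydrophilic spacer positions in the IDRs diverge at `spacer_rate`
#' (substitutions drawn from a polar alphabet), hydrophobic sticker
#' positions are substituted only within the hydrophobic class at
#' `class_rate`, and the conserved region mutates at `cr_rate`. With
#' `n_clades = 2` the ensemble splits into clades derived from ancestors
#' separated by `clade_divergence`, producing a bimodal distance
#' distribution (fish versus tetrapod style).
#'
#' @param n Number of sequences.
#' @param spacer_rate Per-site substitution probability for IDR spacers.
#' @param class_rate Per-site within-class substitution probability for
#'   hydrophobic IDR residues.
#' @param cr_rate Per-site substitution probability inside the CR.
#' @param n_clades 1 or 2.
#' @param clade_divergence Spacer substitution rate separating the two
#'   clade ancestors.
#' @param template Template [protein_record()].
#' @param boundaries A [domain_partition()].
#' @param scheme A [residue_classes()].
#' @param seed Integer seed.
#' @return List with `records` (list of [protein_record()]) and `truth`
#'   (anchor cluster centers of the template, clade assignment, rates).
#' @export
gen_homologs <- function(n = 50L, spacer_rate = 0.3, class_rate = 0.02,
                         cr_rate = 0.02, n_clades = 1L,
                         clade_divergence = 0.25,
                         template = tdp43_ctd(),
                         boundaries = domain_partition(),
                         scheme = residue_classes(), seed = 1L) {
  for (r in c(spacer_rate, class_rate, cr_rate, clade_divergence)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_clades %in% c(1L, 2L))
  set.seed(seed)
  # spacer alphabet: small/polar residues that stay near the hydrophilic
  # baseline of the Fauchere-Pliska scale (A and P are excluded: both carry
  # appreciable hydrophobicity and would erode the sticker/spacer contrast)
  polar <- c("G", "S", "N", "Q")
  ch0 <- record_residues(template)
  pos <- record_positions(template)
  in_idr <- rep(FALSE, length(pos))
  for (nm in c("IDR1", "IDR2")) {
    iv <- boundaries[[nm]]
    in_idr <- in_idr | (pos >= iv[1] & pos <= iv[2])
  }
  in_cr <- pos >= boundaries$CR[1] & pos <= boundaries$CR[2]
  is_phi <- ch0 %in% scheme$hydrophobic
  spacer_idx <- which(in_idr & !is_phi)
  phi_idx <- which(in_idr & is_phi)
  cr_idx <- which(in_cr)
  mutate_seq <- function(ch, s_rate) {
    hit <- spacer_idx[runif(length(spacer_idx)) < s_rate]
    ch[hit] <- sample(polar, length(hit), replace = TRUE)
    hit <- phi_idx[runif(length(phi_idx)) < class_rate]
    ch[hit] <- sample(scheme$hydrophobic, length(hit), replace = TRUE)
    hit <- cr_idx[runif(length(cr_idx)) < cr_rate]
    ch[hit] <- sample(polar, length(hit), replace = TRUE)
    ch
  }
  ancestors <- list(ch0)
  if (n_clades == 2L) ancestors[[2]] <- mutate_seq(ch0, clade_divergence)
  clade <- rep_len(seq_len(n_clades), n)
  records <- lapply(seq_len(n), function(i) {
    ch <- mutate_seq(ancestors[[clade[i]]], spacer_rate)
    protein_record(sprintf("homolog_%03d", i), paste(ch, collapse = ""),
                   template$numbering_offset)
  })
  names(records) <- vapply(records, `[[`, character(1), "id")
  anchors <- ctd_clusters(template, boundaries, scheme = scheme)$center
  list(records = records,
       truth = list(anchors = anchors, clade = clade,
                    spacer_rate = spacer_rate, class_rate = class_rate,
                    cr_rate = cr_rate, seed = seed))
}

#' Generate a nucleus population with a known saturation concentration
#'
#' Record-level population model of the condensate reporter assay:
#' transfected nuclei draw log-normal expression levels; the probability of
#' carrying condensates follows a logistic function of nuclear intensity
#' centered on the true `csat` (cell-to-cell variability makes the
#' threshold soft); condensed nuclei carry 1 + Poisson droplets. An
#' untransfected fraction and a matched non-transfected control population
#' sit at autofluorescence background.
#'
#' @param n Number of nuclei.
#' @param csat True saturation intensity (a.u.).
#' @param expression_meanlog,expression_sdlog Log-normal expression of
#'   transfected nuclei; the default median of 300 a.u. puts the default
#'   `csat` of 100 a.u. at roughly a third of the typical expression
#'   level, the wild-type regime.
#' @param logistic_scale Softness of the condensation threshold (a.u.).
#' @param untransfected_frac Fraction of untransfected nuclei in the field.
#' @param background_meanlog,background_sdlog Autofluorescence background.
#' @param n_control Size of the non-transfected control sample.
#' @param mean_droplets Mean extra droplets per condensed nucleus.
#' @param seed Integer seed.
#' @return List with `records` (data frame `intensity`, `n_droplets`),
#'   `control` (numeric vector) and `truth`.
#' @export
gen_nucleus_population <- function(n = 2000L, csat = 100,
                                   expression_meanlog = log(300),
                                   expression_sdlog = 0.8,
                                   logistic_scale = 15,
                                   untransfected_frac = 0.2,
                                   background_meanlog = log(5),
                                   background_sdlog = 0.5,
                                   n_control = 1000L, mean_droplets = 2,
                                   seed = 1L) {
  set.seed(seed)
  untr <- runif(n) < untransfected_frac
  intensity <- numeric(n)
  intensity[untr] <- rlnorm(sum(untr), background_meanlog, background_sdlog)
  intensity[!untr] <- rlnorm(sum(!untr), expression_meanlog,
                             expression_sdlog)
  cond <- logical(n)
  p <- plogis((intensity[!untr] - csat) / logistic_scale)
  cond[!untr] <- rbinom(sum(!untr), 1L, p) == 1L
  n_droplets <- integer(n)
  n_droplets[cond] <- 1L + stats::rpois(sum(cond), mean_droplets)
  control <- rlnorm(n_control, background_meanlog, background_sdlog)
  list(records = data.frame(intensity = intensity,
                            n_droplets = n_droplets),
       control = control,
       truth = list(csat = csat, transfected = !untr, cond = cond,
                    seed = seed))
}

# draw k non-overlapping disk centers inside a box by rejection sampling;
# partial = TRUE returns however many fitted instead of erroring
.place_disks <- function(k, lo_r, hi_r, lo_c, hi_c, radius, min_gap,
                         max_tries = 5000L, partial = FALSE) {
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < k) {
    tries <- tries + 1L
    if (tries > max_tries) {
      if (partial) return(centers)
      stop("cannot place disks without overlap: field too crowded",
           call. = FALSE)
    }
    cand <- c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
    if (!nrow(centers) ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
              (2 * radius + min_gap)^2)) {
      centers <- rbind(centers, cand)
    }
  }
  centers
}

#' Generate a two-channel field of nuclei with planted droplets
#'
#' Synthetic counterpart of a projected confocal field: disk-shaped nuclei
#' on a dark background in the nuclear-stain channel; in the reporter
#' channel, transfected nuclei carry log-normal expression and nuclei whose
#' expression exceeds the true `csat` contain planted circular droplets
#' (dense phase at `dense_ratio` times the dilute level). Gaussian noise is
#' added at a signal-to-noise ratio defined on the droplet contrast.
#'
#' @param n_cells Number of nuclei in the field.
#' @param size Field edge length in pixels.
#' @param nucleus_radius Nucleus radius (pixels).
#' @param csat Expression threshold above which droplets form.
#' @param expression_meanlog,expression_sdlog Log-normal expression.
#' @param untransfected_frac Fraction of nuclei at background reporter
#'   level.
#' @param droplet_radius Droplet radius in pixels.
#' @param mean_droplets Mean extra droplets per condensed nucleus (count is
#'   1 + Poisson).
#' @param dense_ratio Dense/dilute intensity ratio inside droplets.
#' @param snr Droplet contrast divided by noise SD; `Inf` for noise-free.
#' @param background Reporter background level (a.u.).
#' @param nuclear_level Nuclear-stain intensity of nuclei.
#' @param seed Integer seed.
#' @return List with `nuclear`, `reporter` (matrices) and `truth` (per-cell
#'   data frame: center, radius, expression, transfected, cond,
#'   n_droplets; plus droplet centers).
#' @export
gen_nuclei_images <- function(n_cells = 12L, size = 220L,
                              nucleus_radius = 13, csat = 100,
                              expression_meanlog = log(300),
                              expression_sdlog = 0.8,
                              untransfected_frac = 0.15,
                              droplet_radius = 2.6, mean_droplets = 2,
                              dense_ratio = 5, snr = Inf, background = 2,
                              nuclear_level = 1000, seed = 1L) {
  set.seed(seed)
  margin <- nucleus_radius + 3
  centers <- .place_disks(n_cells, margin, size - margin, margin,
                          size - margin, nucleus_radius, min_gap = 4)
  untr <- runif(n_cells) < untransfected_frac
  expression <- ifelse(untr, rlnorm(n_cells, log(5), 0.4),
                       rlnorm(n_cells, expression_meanlog,
                              expression_sdlog))
  cond <- !untr & expression > csat
  n_droplets <- ifelse(cond, 1L + stats::rpois(n_cells, mean_droplets), 0L)
  nuclear <- matrix(0, size, size)
  reporter <- matrix(background, size, size)
  rr <- row(nuclear); cc <- col(nuclear)
  droplet_centers <- list()
  for (i in seq_len(n_cells)) {
    inside <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <=
      nucleus_radius^2
    nuclear[inside] <- nuclear_level
    # dilute phase: condensed nuclei are depleted relative to expression
    dilute <- if (cond[i]) expression[i] / (1 + 0.3) else expression[i]
    reporter[inside] <- dilute
    if (n_droplets[i] > 0L) {
      dc <- .place_disks(n_droplets[i],
                         centers[i, 1] - nucleus_radius + droplet_radius + 2,
                         centers[i, 1] + nucleus_radius - droplet_radius - 2,
                         centers[i, 2] - nucleus_radius + droplet_radius + 2,
                         centers[i, 2] + nucleus_radius - droplet_radius - 2,
                         droplet_radius, min_gap = 3, partial = TRUE)
      # keep only droplets fully inside the nucleus
      keep <- (dc[, 1] - centers[i, 1])^2 + (dc[, 2] - centers[i, 2])^2 <=
        (nucleus_radius - droplet_radius - 1)^2
      dc <- dc[keep, , drop = FALSE]
      n_droplets[i] <- nrow(dc)
      if (n_droplets[i] == 0L) cond[i] <- FALSE
      for (d in seq_len(nrow(dc))) {
        din <- (rr - dc[d, 1])^2 + (cc - dc[d, 2])^2 <= droplet_radius^2
        reporter[din] <- dilute * dense_ratio
      }
      droplet_centers[[i]] <- dc
    } else {
      droplet_centers[[i]] <- matrix(numeric(0), ncol = 2)
    }
  }
  if (is.finite(snr)) {
    # SNR is defined on the faintest planted droplet: its dense-dilute
    # contrast divided by the noise SD
    dilute_all <- ifelse(cond, expression / 1.3, expression)
    contrast <- if (any(cond & n_droplets > 0L)) {
      min(dilute_all[cond & n_droplets > 0L]) * (dense_ratio - 1)
    } else {
      median(expression[!untr]) * (dense_ratio - 1)
    }
    noise_sd <- contrast / snr
    nuclear <- nuclear + matrix(rnorm(size^2, 0, nuclear_level / (4 * snr)),
                                size, size)
    reporter <- reporter + matrix(rnorm(size^2, 0, noise_sd), size, size)
    nuclear[nuclear < 0] <- 0
    reporter[reporter < 0] <- 0
  }
  truth <- data.frame(cell = seq_len(n_cells), row = centers[, 1],
                      col = centers[, 2], radius = nucleus_radius,
                      expression = expression, transfected = !untr,
                      cond = cond, n_droplets = n_droplets)
  list(nuclear = nuclear, reporter = reporter,
       truth = list(cells = truth, droplet_centers = droplet_centers,
                    csat = csat, seed = seed))
}

#' Generate half-bleach FRAP traces with known dynamics
#'
#' Hemisphere-ratio traces following the single-exponential recovery
#' `I_t = I_t0 + (I_pre - I_t0) * A * (1 - exp(-k t))` with Gaussian noise
#' specified on the normalized recovery scale (`noise_sd` is the SD of
#' FR-scale noise, converted into ratio units internally). The unbleached
#' hemisphere is held at a constant plateau so the bleached-hemisphere
#' intensity is `ratio * unbleached`.
#'
#' @param n Number of droplets (traces).
#' @param A Mobile fraction(s) in \[0, 1\], recycled over traces.
#' @param k Recovery rate(s) in 1/s, recycled over traces.
#' @param dt Sampling interval (s).
#' @param n_pre,n_post Pre- and post-bleach frame counts.
#' @param i_pre,i_t0 Pre-bleach and first post-bleach hemisphere ratios.
#' @param noise_sd Gaussian noise SD on the FR scale.
#' @param unbleached_level Constant unbleached-hemisphere intensity (a.u.).
#' @param seed Integer seed.
#' @return List with `traces` (list of [frap_trace()]) and `truth` (data
#'   frame `id`, `A`, `k`).
#' @export
gen_frap <- function(n = 10L, A = 0.8, k = 0.1, dt = 0.5, n_pre = 5L,
                     n_post = 60L, i_pre = 1.0, i_t0 = 0.4,
                     noise_sd = 0.02, unbleached_level = 100, seed = 1L) {
  if (any(A < 0 | A > 1)) stop("A must lie in [0, 1]", call. = FALSE)
  if (any(k <= 0)) stop("k must be positive", call. = FALSE)
  set.seed(seed)
  A <- rep_len(A, n); k <- rep_len(k, n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    t_all <- seq_len(n_pre + n_post) * dt
    post_t <- (seq_len(n_post) - 1L) * dt
    ratio <- c(rep(i_pre, n_pre),
               i_t0 + (i_pre - i_t0) * A[i] * (1 - exp(-k[i] * post_t)))
    if (noise_sd > 0) {
      ratio <- ratio + rnorm(length(ratio), 0, noise_sd * (i_pre - i_t0))
    }
    traces[[i]] <- frap_trace(
      time = t_all, bleached = ratio * unbleached_level,
      unbleached = rep(unbleached_level, length(t_all)),
      prebleach = c(rep(TRUE, n_pre), rep(FALSE, n_post)),
      id = sprintf("droplet_%02d", i))
  }
  names(traces) <- vapply(traces, `[[`, character(1), "id")
  list(traces = traces,
       truth = data.frame(id = names(traces), A = A, k = k))
}

#' Default spillover matrix for the three-colour splicing reporter
#'
#' @param bfp_gfp,gfp_mcherry,mcherry_gfp Off-diagonal spillover fractions.
#' @return 3x3 spillover matrix over BFP, GFP, mCherry.
#' @export
default_spillover <- function(bfp_gfp = 0.05, gfp_mcherry = 0.10,
                              mcherry_gfp = 0.02) {
  m <- diag(3)
  dimnames(m) <- list(FLUOR_CHANNELS, FLUOR_CHANNELS)
  m["BFP", "GFP"] <- bfp_gfp
  m["GFP", "mCherry"] <- gfp_mcherry
  m["mCherry", "GFP"] <- mcherry_gfp
  m
}

#' Generate three-colour flow events for splicing-reporter variants
#'
#' Each variant is a cell population carrying the bidirectional
#' TDP43/splicing-reporter plasmid: BFP (TDP43 abundance) and GFP (reporter
#' expression) are correlated log-normals; the true per-cell splicing
#' ratio follows the saturating dose-response
#' `r(BFP) = baseline + r_max * BFP / (BFP + K)` with multiplicative noise
#' whose coefficient of variation shrinks with expression (so ratios
#' converge towards a set-point at high TDP43 levels); mCherry is
#' `r * GFP`. Debris, doublets and untransfected events are included, and
#' the chosen spillover matrix is applied to produce observed intensities.
#'
#' @param variants Named list; each element a list with `r_max`, `K`,
#'   `baseline` (dose-response parameters).
#' @param n_events Events per variant.
#' @param transfected_frac Fraction of BFP-positive (transfected) cells.
#' @param debris_frac,doublet_frac Fractions of debris and doublet events.
#' @param bfp_meanlog,bfp_sdlog Log-normal TDP43 expression.
#' @param ratio_cv Multiplicative noise CV of the splicing ratio at
#'   `BFP = K`.
#' @param cv_exponent Exponent of the CV shrinkage with expression.
#' @param spillover Spillover matrix (see [default_spillover()]).
#' @param seed Integer seed.
#' @return List with `events` (named list of data frames with scatter and
#'   observed fluorescence columns), `spillover` and `truth` (per-variant
#'   parameters and per-event labels).
#' @export
gen_flow <- function(variants = list(WT = list(r_max = 0.6, K = 2000,
                                               baseline = 0.05)),
                     n_events = 40000L, transfected_frac = 0.7,
                     debris_frac = 0.05, doublet_frac = 0.05,
                     bfp_meanlog = log(5000), bfp_sdlog = 1.0,
                     ratio_cv = 0.35, cv_exponent = 0.35,
                     spillover = default_spillover(), seed = 1L) {
  stopifnot(!is.null(names(variants)))
  if (det(spillover) == 0) stop("spillover matrix is singular",
                                call. = FALSE)
  set.seed(seed)
  out <- list(); labels <- list()
  for (v in names(variants)) {
    pars <- variants[[v]]
    n <- n_events
    kind <- sample(c("cell", "debris", "doublet"), n, replace = TRUE,
                   prob = c(1 - debris_frac - doublet_frac, debris_frac,
                            doublet_frac))
    transfected <- kind != "debris" & runif(n) < transfected_frac
    fsc <- rlnorm(n, log(5e4), 0.2)
    fsc[kind == "debris"] <- rlnorm(sum(kind == "debris"), log(3e3), 0.4)
    fsc_h <- fsc * 0.95 * rlnorm(n, 0, 0.03)
    fsc[kind == "doublet"] <- 2 * fsc[kind == "doublet"]
    ssc <- rlnorm(n, log(3e4), 0.3)
    ssc[kind == "debris"] <- rlnorm(sum(kind == "debris"), log(1.5e3), 0.4)
    bfp <- rlnorm(n, log(120), 0.5)  # autofluorescence
    bfp[transfected] <- rlnorm(sum(transfected), bfp_meanlog, bfp_sdlog)
    gfp <- rlnorm(n, log(50), 0.4)
    gfp[transfected] <- 0.4 * bfp[transfected] *
      rlnorm(sum(transfected), 0, 0.3)
    r_true <- rep(NA_real_, n)
    mch <- rlnorm(n, log(30), 0.4)
    if (any(transfected)) {
      b <- bfp[transfected]
      r_mean <- pars$baseline + pars$r_max * b / (b + pars$K)
      cv <- ratio_cv * (pars$K / b)^cv_exponent
      r_cell <- r_mean * rlnorm(sum(transfected), -cv^2 / 2, cv)
      r_true[transfected] <- r_cell
      mch[transfected] <- r_cell * gfp[transfected]
    }
    true_mat <- cbind(BFP = bfp, GFP = gfp, mCherry = mch)
    obs <- true_mat %*% spillover
    ev <- data.frame(FSC_A = fsc, FSC_H = fsc_h, SSC_A = ssc,
                     BFP = obs[, "BFP"], GFP = obs[, "GFP"],
                     mCherry = obs[, "mCherry"])
    out[[v]] <- ev
    labels[[v]] <- data.frame(kind = kind, transfected = transfected,
                              true_ratio = r_true)
  }
  list(events = out, spillover = spillover,
       truth = list(variants = variants, labels = labels,
                    transfected_frac = transfected_frac, seed = seed))
}
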