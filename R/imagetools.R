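# Low-level 2-D image primitives used by the condensate quantification
# pipeline. Images are numeric matrices indexed [row, col] (1-based, R
# convention); z-stacks are arrays with dim = c(nz, nrow, ncol).

#' Project a z-stack to a single 2-D image
#'
#' @param stack Array with dim `c(nz, nrow, ncol)`, or a matrix (returned
#'   unchanged).
#' @param method `"max"` (default) for a maximum-intensity projection, or
#'   `"focus"` for a focus-weighted mean where each plane is weighted by the
#'   variance of its Laplacian (a standard sharpness score).
#' @return Numeric matrix `nrow x ncol`.
#' @export
project_stack <- function(stack, method = c("max", "focus")) {
  method <- match.arg(method)
  if (is.matrix(stack)) return(stack)
  if (!(is.array(stack) && length(dim(stack)) == 3L)) {
    stop("stack must be a matrix or a 3-D array (z, row, col)",
         call. = FALSE)
  }
  nz <- dim(stack)[1]
  if (nz == 0L) stop("empty stack", call. = FALSE)
  if (nz == 1L) return(stack[1, , ])
  if (method == "max") return(apply(stack, c(2, 3), max))
  w <- vapply(seq_len(nz), function(z) {
    plane <- stack[z, , ]
    lap <- 4 * plane -
      rbind(plane[-1, ], plane[nrow(plane), ]) -
      rbind(plane[1, ], plane[-nrow(plane), ]) -
      cbind(plane[, -1], plane[, ncol(plane)]) -
      cbind(plane[, 1], plane[, -ncol(plane)])
    stats::var(as.numeric(lap))
  }, numeric(1))
  if (sum(w) <= 0) w <- rep(1, nz)
  out <- 0 * stack[1, , ]
  for (z in seq_len(nz)) out <- out + w[z] * stack[z, , ]
  out / sum(w)
}

#' Otsu threshold of an image
#'
#' Maximizes the between-class variance over a 256-bin histogram.
#'
#' @param img Numeric matrix.
#' @param levels Number of histogram bins.
#' @return Threshold on the intensity scale of `img`; pixels strictly above
#'   it are foreground.
#' @export
otsu_threshold <- function(img, levels = 256L) {
  x <- as.numeric(img)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Label connected foreground components
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (default) or 8.
#' @return Integer matrix of labels (0 = background), numbered in raster
#'   order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 4L) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  id <- match(seq_len(nr * nc), idx)  # pixel -> vertex id
  edges <- integer(0)
  add_pairs <- function(a, b) {
    ok <- mask[a] & mask[b]
    rbind(id[a[ok]], id[b[ok]])
  }
  # right neighbours
  a <- which(col(mask) < nc & mask)
  e1 <- add_pairs(a, a + nr)
  # down neighbours
  a <- which(row(mask) < nr & mask)
  e2 <- add_pairs(a, a + 1L)
  elist <- cbind(e1, e2)
  if (connectivity == 8L) {
    a <- which(row(mask) < nr & col(mask) < nc & mask)
    e3 <- add_pairs(a, a + nr + 1L)
    a <- which(row(mask) > 1L & col(mask) < nc & mask)
    e4 <- add_pairs(a, a + nr - 1L)
    elist <- cbind(elist, e3, e4)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (ncol(elist)) g <- igraph::add_edges(g, as.vector(elist))
  memb <- igraph::components(g)$membership
  # renumber in order of first appearance (column-major raster scan)
  lab[idx] <- match(memb, unique(memb))
  lab
}

#' Fill holes in a binary mask
#'
#' Background components not connected to the image border are converted to
#' foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- setdiff(border, 0L)
  mask | (bg != 0L & !(bg %in% border))
}

#' Chamfer distance transform
#'
#' Two-pass 3-4 chamfer approximation of the Euclidean distance of every
#' foreground pixel to the nearest background pixel.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of distances (0 on background).
#' @export
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- 3 * (nr + nc)
  d <- matrix(0, nr + 2L, nc + 2L)
  d[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(mask, big, 0)
  for (i in 2:(nr + 1L)) for (j in 2:(nc + 1L)) {
    if (d[i, j] > 0) {
      d[i, j] <- min(d[i, j], d[i - 1L, j] + 3, d[i, j - 1L] + 3,
                     d[i - 1L, j - 1L] + 4, d[i - 1L, j + 1L] + 4)
    }
  }
  for (i in (nr + 1L):2) for (j in (nc + 1L):2) {
    if (d[i, j] > 0) {
      d[i, j] <- min(d[i, j], d[i + 1L, j] + 3, d[i, j + 1L] + 3,
                     d[i + 1L, j + 1L] + 4, d[i + 1L, j - 1L] + 4)
    }
  }
  d[2:(nr + 1L), 2:(nc + 1L)] / 3
}

# Greedily thinned local maxima of img restricted to mask: strongest first,
# accepted when at least min_sep pixels (Euclidean) from all accepted peaks.
.local_maxima <- function(img, mask, min_value = -Inf, min_sep = 1) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  is_max <- ctr >= pad[1:nr, 2:(nc + 1L)] & ctr >= pad[3:(nr + 2L), 2:(nc + 1L)] &
    ctr >= pad[2:(nr + 1L), 1:nc] & ctr >= pad[2:(nr + 1L), 3:(nc + 2L)] &
    ctr >= pad[1:nr, 1:nc] & ctr >= pad[1:nr, 3:(nc + 2L)] &
    ctr >= pad[3:(nr + 2L), 1:nc] & ctr >= pad[3:(nr + 2L), 3:(nc + 2L)]
  cand <- which(is_max & mask & img >= min_value)
  if (!length(cand)) return(cbind(row = integer(0), col = integer(0)))
  cand <- cand[order(-img[cand], cand)]
  rr <- (cand - 1L) %% nr + 1L
  cc <- (cand - 1L) %/% nr + 1L
  keep <- integer(0)
  for (i in seq_along(cand)) {
    if (!length(keep) ||
        all((rr[keep] - rr[i])^2 + (cc[keep] - cc[i])^2 >= min_sep^2)) {
      keep <- c(keep, i)
    }
  }
  cbind(row = rr[keep], col = cc[keep])
}
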