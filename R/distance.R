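# Sequence divergence as length-normalized Levenshtein distance.

#' Normalized edit distance between two sequences
#'
#' Levenshtein (edit) distance rescaled to a reference length of 100
#' residues, the divergence measure used to compare homolog collections of
#' unequal length. Normalization divides by the mean of the two lengths by
#' default; dividing by the longer length is available as an alternative.
#'
#' @param a,b Non-empty sequences (character strings or [protein_record()]).
#' @param normalization `"mean"` (default) or `"max"` length normalization.
#' @return Distance per 100 aa: `100 * lev(a, b) / norm(len_a, len_b)`.
#'   Symmetric, non-negative and zero iff the sequences are identical.
#' @examples
#' normalized_edit_distance("KITTEN", "SITTING")  # 100 * 3 / 6.5
#' @export
normalized_edit_distance <- function(a, b,
                                     normalization = c("mean", "max")) {
  normalization <- match.arg(normalization)
  a <- if (inherits(a, "protein_record")) a$sequence else as.character(a)
  b <- if (inherits(b, "protein_record")) b$sequence else as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty",
                                     call. = FALSE)
  lev <- as.numeric(adist(a, b))
  denom <- switch(normalization,
                  mean = (nchar(a) + nchar(b)) / 2,
                  max = max(nchar(a), nchar(b)))
  100 * lev / denom
}

#' Pairwise normalized edit distances of a collection
#'
#' @param records List of [protein_record()] objects (or named character
#'   vector of sequences) with unique ids; at least two.
#' @inheritParams normalized_edit_distance
#' @return List of class `distance_matrix` with elements `matrix` (symmetric,
#'   zero diagonal), `mean` and `sd` of the off-diagonal entries, and `n`.
#' @export
pairwise_distance_matrix <- function(records,
                                     normalization = c("mean", "max")) {
  normalization <- match.arg(normalization)
  if (is.character(records)) {
    ids <- names(records)
    seqs <- unname(records)
  } else {
    ids <- vapply(records, `[[`, character(1), "id")
    seqs <- vapply(records, `[[`, character(1), "sequence")
  }
  if (length(seqs) < 2L) stop("need at least two records", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) stop("duplicate record ids", call. = FALSE)
  lev <- adist(seqs)
  len <- nchar(seqs)
  denom <- switch(normalization,
                  mean = outer(len, len, function(i, j) (i + j) / 2),
                  max = outer(len, len, pmax))
  m <- 100 * lev / denom
  dimnames(m) <- list(ids, ids)
  off <- m[upper.tri(m)]
  structure(list(matrix = m, mean = mean(off), sd = sd(off),
                 n = length(seqs)),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d sequences; off-diagonal %.2f +/- %.2f per 100 aa\n",
              x$n, x$mean, x$sd))
  invisible(x)
}
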