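# Amino-acid composition and hydrophobic density.

seq_chars <- function(x) {
  s <- if (inherits(x, "protein_record")) x$sequence else toupper(as.character(x))
  if (!nzchar(s)) stop("sequence must be non-empty", call. = FALSE)
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(ch), AA20)
  if (length(bad)) stop("non-canonical residues: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ch
}

#' Amino-acid composition per 100 residues
#'
#' For a single sequence, the frequency of each of the 20 residues per 100
#' residues (summing to 100). For a collection, the per-sequence profiles
#' together with their mean and standard deviation per residue, which is how
#' compositional conservation across homolog ensembles is summarized.
#'
#' @param x A sequence (string or [protein_record()]) or a list of them.
#' @return For a single sequence, a named numeric vector over the 20
#'   residues. For a collection, a list of class `composition_profile` with
#'   `profiles` (sequences x residues matrix), `mean` and `sd`.
#' @examples
#' composition("MF")  # M 50, F 50
#' @export
composition <- function(x) {
  if (!inherits(x, "protein_record") &&
      (is.list(x) || (is.character(x) && length(x) > 1L))) {
    xs <- if (is.character(x)) as.list(x) else x
    profiles <- t(vapply(xs, composition, numeric(20L)))
    rownames(profiles) <- if (!is.null(names(xs))) names(xs) else
      vapply(seq_along(xs), function(i) {
        if (inherits(xs[[i]], "protein_record")) xs[[i]]$id else paste0("seq", i)
      }, character(1))
    return(structure(list(profiles = profiles,
                          mean = colMeans(profiles),
                          sd = apply(profiles, 2, sd)),
                     class = "composition_profile"))
  }
  ch <- seq_chars(x)
  100 * table(factor(ch, levels = AA20))[AA20] / length(ch) ->
    freq
  out <- as.numeric(freq)
  names(out) <- AA20
  out
}

#' Hydrophobic residue density per 100 residues
#'
#' Number of hydrophobic (Phi) residues normalized to a reference length of
#' 100 amino acids, the per-IDR sticker density statistic.
#'
#' @param x Sequence (string or [protein_record()]).
#' @param scheme A [residue_classes()]; the `hydrophobic` set is used.
#' @param class Which residue class of `scheme` to count.
#' @return `100 * count / length`.
#' @examples
#' hydrophobic_density("FFSS")  # 50
#' @export
hydrophobic_density <- function(x, scheme = residue_classes(),
                                class = "hydrophobic") {
  if (is.null(scheme[[class]])) stop("unknown residue class '", class, "'",
                                     call. = FALSE)
  ch <- seq_chars(x)
  100 * sum(ch %in% scheme[[class]]) / length(ch)
}
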