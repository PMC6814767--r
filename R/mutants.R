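# Constraint-preserving mutant design for the TDP43 CTD: class
# substitutions (CR protected), coordinate-checked point mutations, and
# composition-preserving regrouping of hydrophobic clusters.

#' Mutant specifications
#'
#' Three kinds of CTD mutants are expressible:
#' * `class_substitution()` replaces every residue of one or more residue
#'   classes (or literal residues) by a single target residue, by default
#'   only inside the IDRs (the conserved region is left untouched).
#' * `point_mutations()` applies explicit substitutions in full-length
#'   coordinates, with a mandatory reference-residue check that guards
#'   against numbering mistakes.
#' * `cluster_regroup()` relocates hydrophobic residues so that the CTD
#'   carries fewer, stronger clusters while preserving the residue multiset
#'   exactly (see [regroup_clusters()]).
#'
#' @param name Mutant name (used in FASTA headers).
#' @param from For `class_substitution`: character vector of residue class
#'   names (see [residue_classes()]) and/or literal residues.
#' @param to Single target residue.
#' @param region Interval names of the domain partition defining where the
#'   substitution applies; default `c("IDR1", "IDR2")`.
#' @return A `mutant_spec` object.
#' @export
class_substitution <- function(name, from, to,
                               region = c("IDR1", "IDR2")) {
  stopifnot(length(to) == 1L, to %in% AA20)
  structure(list(name = name, kind = "class_substitution", from = from,
                 to = to, region = region),
            class = "mutant_spec")
}

#' @rdname class_substitution
#' @param mutations Character vector like `c("W385G", "G368W")` or a data
#'   frame with columns `position`, `from`, `to`.
#' @export
point_mutations <- function(name, mutations) {
  if (is.character(mutations)) {
    m <- regmatches(mutations,
                    regexec("^([A-Z])([0-9]+)([A-Z])$", mutations))
    if (any(vapply(m, length, integer(1)) != 4L)) {
      stop("cannot parse point mutations: expected e.g. 'W385G'",
           call. = FALSE)
    }
    mutations <- data.frame(
      position = as.integer(vapply(m, `[`, character(1), 3L)),
      from = vapply(m, `[`, character(1), 2L),
      to = vapply(m, `[`, character(1), 4L))
  }
  stopifnot(all(c("position", "from", "to") %in% names(mutations)),
            all(mutations$to %in% AA20))
  structure(list(name = name, kind = "point_mutations",
                 mutations = mutations),
            class = "mutant_spec")
}

#' @rdname class_substitution
#' @param target_count Desired number of IDR clusters after regrouping
#'   (typically 6, 4 or 2 starting from the wild-type 8).
#' @export
cluster_regroup <- function(name, target_count) {
  structure(list(name = name, kind = "cluster_regroup",
                 target_count = as.integer(target_count)),
            class = "mutant_spec")
}

#' @export
print.mutant_spec <- function(x, ...) {
  cat(sprintf("<mutant_spec> %s (%s)\n", x$name, x$kind))
  invisible(x)
}

#' Catalog of the CTD mutants studied in this package
#'
#' Named list of [class_substitution()], [point_mutations()] and
#' [cluster_regroup()] specs covering the compositional series (Phi-S, F-S,
#' FYW-S, FYW-L, VLIM-S, VLIM-F, R-K, K-R, KRED-S, M-S, M-V, F-Y, W-S), the
#' single and compensatory point mutants (W385G, G348V, G348F, G309F,
#' G309S, G368W, W385G/G368W) and the cluster-spacing series (6xPhi, 4xPhi,
#' 2xPhi).
#'
#' @return Named list of `mutant_spec` objects.
#' @export
mutant_catalog <- function() {
  specs <- list(
    class_substitution("Phi-S", "hydrophobic", "S"),
    class_substitution("F-S", "F", "S"),
    class_substitution("FYW-S", "aromatic", "S"),
    class_substitution("FYW-L", "aromatic", "L"),
    class_substitution("VLIM-S", "aliphatic", "S"),
    class_substitution("VLIM-F", "aliphatic", "F"),
    class_substitution("R-K", "R", "K"),
    class_substitution("K-R", "K", "R"),
    class_substitution("KRED-S", "charged", "S"),
    class_substitution("M-S", "M", "S"),
    class_substitution("M-V", "M", "V"),
    class_substitution("F-Y", "F", "Y"),
    class_substitution("W-S", "W", "S"),
    point_mutations("W385G", "W385G"),
    point_mutations("G348V", "G348V"),
    point_mutations("G348F", "G348F"),
    point_mutations("G309F", "G309F"),
    point_mutations("G309S", "G309S"),
    point_mutations("G368W", "G368W"),
    point_mutations("W385G/G368W", c("W385G", "G368W")),
    cluster_regroup("6xPhi", 6L),
    cluster_regroup("4xPhi", 4L),
    cluster_regroup("2xPhi", 2L)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Apply a mutant specification to a record
#'
#' Class substitutions act only inside the stated region (by default the two
#' IDRs, protecting the conserved region); point mutations use full-length
#' coordinates and fail loudly if the reference residue does not match;
#' cluster regrouping delegates to [regroup_clusters()].
#'
#' @param record A [protein_record()].
#' @param spec A `mutant_spec` (by name from [mutant_catalog()] or
#'   constructed directly). A plain string is looked up in the catalog.
#' @param scheme A [residue_classes()].
#' @param boundaries A [domain_partition()].
#' @return The mutant [protein_record()], id `"<record id>|<mutant name>"`.
#' @examples
#' mut <- apply_mutant(tdp43_ctd(), "W385G")
#' record_residues(mut)[record_positions(mut) == 385]  # "G"
#' @export
apply_mutant <- function(record, spec, scheme = residue_classes(),
                         boundaries = domain_partition()) {
  if (is.character(spec)) {
    cat_ <- mutant_catalog()
    if (!spec %in% names(cat_)) stop("unknown catalog mutant '", spec, "'",
                                     call. = FALSE)
    spec <- cat_[[spec]]
  }
  stopifnot(inherits(spec, "mutant_spec"))
  ch <- record_residues(record)
  pos <- record_positions(record)
  if (spec$kind == "class_substitution") {
    res_set <- unique(unlist(lapply(spec$from, function(f) {
      if (f %in% names(scheme)) scheme[[f]]
      else if (f %in% AA20) f
      else stop("unknown class or residue '", f, "'", call. = FALSE)
    })))
    in_region <- rep(FALSE, length(pos))
    for (nm in spec$region) {
      iv <- boundaries[[nm]]
      if (is.null(iv)) stop("unknown region '", nm, "'", call. = FALSE)
      in_region <- in_region | (pos >= iv[1] & pos <= iv[2])
    }
    ch[in_region & ch %in% res_set] <- spec$to
  } else if (spec$kind == "point_mutations") {
    for (i in seq_len(nrow(spec$mutations))) {
      p <- spec$mutations$position[i]
      j <- match(p, pos)
      if (is.na(j)) stop(sprintf("position %d outside record '%s'", p,
                                 record$id), call. = FALSE)
      if (ch[j] != spec$mutations$from[i]) {
        stop(sprintf(
          "reference mismatch at %d: record has %s, spec expects %s",
          p, ch[j], spec$mutations$from[i]), call. = FALSE)
      }
      ch[j] <- spec$mutations$to[i]
    }
  } else if (spec$kind == "cluster_regroup") {
    return(regroup_clusters(record, spec$target_count, scheme = scheme,
                            boundaries = boundaries,
                            name = paste0(record$id, "|", spec$name)))
  } else {
    stop("unknown mutant kind '", spec$kind, "'", call. = FALSE)
  }
  protein_record(paste0(record$id, "|", spec$name),
                 paste(ch, collapse = ""), record$numbering_offset)
}

#' Regroup hydrophobic clusters without changing composition
#'
#' Reduces the number of IDR hydrophobic clusters to `target_count` by
#' relocating the hydrophobic residues of donor clusters next to the
#' retained anchor clusters, swapping them with spacer residues. The
#' residue multiset (and hence amino-acid composition and overall
#' hydrophobicity) is preserved exactly, the sequence length is unchanged
#' and the conserved region is never modified. The procedure is greedy and
#' deterministic: clusters are ranked by prominence, the top `target_count`
#' become anchors, donor clusters are dismantled from the N-terminus
#' onwards and each displaced residue is appended to the contiguous
#' hydrophobic block of its nearest anchor, preferring the side facing the
#' donor and breaking ties toward the N-terminus.
#'
#' @param record A [protein_record()] spanning a CTD-like region.
#' @param target_count Desired cluster count; must not exceed the current
#'   count (equal is the identity).
#' @param scheme A [residue_classes()].
#' @param boundaries A [domain_partition()]; moves are confined to IDR1 and
#'   IDR2.
#' @param name Id for the mutant record.
#' @param ... Detection parameters forwarded to [ctd_clusters()].
#' @return The regrouped [protein_record()]. Errors reporting the achieved
#'   count if the target cannot be realized under the shipped detection
#'   defaults.
#' @export
regroup_clusters <- function(record, target_count,
                             scheme = residue_classes(),
                             boundaries = domain_partition(),
                             name = NULL, ...) {
  target_count <- as.integer(target_count)
  if (is.null(name)) name <- sprintf("%s|%dxPhi", record$id, target_count)
  cl <- ctd_clusters(record, boundaries, scheme = scheme, ...)
  cur <- nrow(cl)
  if (target_count > cur) {
    stop(sprintf("target %d exceeds current cluster count %d",
                 target_count, cur), call. = FALSE)
  }
  if (target_count == cur) {
    return(protein_record(name, record$sequence, record$numbering_offset))
  }
  ch <- record_residues(record)
  pos <- record_positions(record)
  idx_of <- function(p) match(p, pos)
  in_idr <- rep(FALSE, length(pos))
  for (nm in c("IDR1", "IDR2")) {
    iv <- boundaries[[nm]]
    in_idr <- in_idr | (pos >= iv[1] & pos <= iv[2])
  }
  is_phi <- function() ch %in% scheme$hydrophobic
  # anchors are allocated per IDR (alternating, starting from the IDR that
  # holds the most prominent cluster) so both IDRs keep stickers, mirroring
  # the architecture of the regrouped variants
  ord <- order(-cl$prominence, -cl$height, cl$center)
  ranked <- cl[ord, , drop = FALSE]
  if (!anyNA(ranked$region) && length(unique(ranked$region)) > 1L) {
    pool <- split(seq_len(nrow(ranked)), ranked$region)
    pool <- pool[order(vapply(pool, min, integer(1)))]  # best region first
    take <- integer(0)
    i <- 1L
    while (length(take) < target_count) {
      r <- 1L + (i - 1L) %% length(pool)
      if (length(pool[[r]])) {
        take <- c(take, pool[[r]][1])
        pool[[r]] <- pool[[r]][-1]
      }
      i <- i + 1L
    }
    anchor_idx <- sort(ord[take])
  } else {
    anchor_idx <- sort(ord[seq_len(target_count)])
  }
  anchors <- cl[anchor_idx, , drop = FALSE]
  donors <- cl[setdiff(seq_len(nrow(cl)), anchor_idx), , drop = FALSE]
  # each IDR hydrophobic residue belongs to its nearest cluster center
  phi_pos <- pos[is_phi() & in_idr]
  owner <- cl$center[apply(abs(outer(phi_pos, cl$center, "-")), 1,
                           which.min)]
  # anchor blocks: the span of hydrophobic residues currently credited to
  # each anchor, grown as donated residues arrive
  span <- cbind(anchors$start, anchors$end)
  for (d in seq_len(nrow(donors))) {
    donor_phi <- phi_pos[owner == donors$center[d]]
    for (p in donor_phi) {
      dist <- abs(anchors$center - donors$center[d])
      a <- which(dist == min(dist))[1]  # tie toward the N-terminal anchor
      # candidate slots flanking the anchor block, preferring the donor side
      sides <- if (donors$center[d] <= anchors$center[a]) c(-1L, 1L) else
        c(1L, -1L)
      placed <- FALSE
      for (s in sides) {
        slot <- if (s < 0L) span[a, 1] - 1L else span[a, 2] + 1L
        # march outward over residues that are already hydrophobic
        while (slot %in% pos && in_idr[idx_of(slot)] &&
               is_phi()[idx_of(slot)]) {
          slot <- slot + s
        }
        if (slot %in% pos && in_idr[idx_of(slot)]) {
          i_slot <- idx_of(slot); i_p <- idx_of(p)
          tmp <- ch[i_slot]; ch[i_slot] <- ch[i_p]; ch[i_p] <- tmp
          span[a, 1] <- min(span[a, 1], slot)
          span[a, 2] <- max(span[a, 2], slot)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("no legal slot found while regrouping clusters", call. = FALSE)
      }
    }
  }
  mut <- protein_record(name, paste(ch, collapse = ""),
                        record$numbering_offset)
  achieved <- nrow(ctd_clusters(mut, boundaries, scheme = scheme, ...))
  if (achieved != target_count) {
    stop(sprintf("regrouping achieved %d clusters, target %d", achieved,
                 target_count), call. = FALSE)
  }
  mut
}
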