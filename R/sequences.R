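#' @importFrom stats approx coef density fivenum glm lm mad median nls optim
#'   plogis predict quantile rbinom rlnorm rnorm runif sd setNames t.test
#'   wilcox.test binomial IQR
#' @importFrom utils adist head tail
NULL

#' Protein record with full-length numbering
#'
#' A minimal container for a protein (sub)sequence that remembers where it
#' sits in the numbering of the full-length protein, so that mutations and
#' cluster positions can be expressed in the familiar UniProt-style
#' coordinates (e.g. W385 in the TDP43 CTD even though the record only
#' spans the CTD).
#'
#' @param id Character identifier.
#' @param sequence Amino-acid string using the canonical 20-letter alphabet
#'   (uppercase).
#' @param numbering_offset Full-length position of residue 1 of this record
#'   (1-based, so a record holding the whole protein has offset 1).
#' @return An object of class `protein_record`: a list with elements `id`,
#'   `sequence`, `numbering_offset`.
#' @examples
#' rec <- protein_record("toy", "GGFGG", 10)
#' record_positions(rec)  # 10:14
#' @export
protein_record <- function(id, sequence, numbering_offset = 1L) {
  stopifnot(is.character(id), length(id) == 1L)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA20)
  if (length(bad)) {
    stop("non-canonical residues in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 1L) {
    stop("numbering_offset must be >= 1", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence,
                 numbering_offset = numbering_offset),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa, positions %d-%d\n", x$id,
              nchar(x$sequence), x$numbering_offset,
              x$numbering_offset + nchar(x$sequence) - 1L))
  invisible(x)
}

#' Full-length positions covered by a record
#' @param record A [protein_record()].
#' @return Integer vector of full-length coordinates, one per residue.
#' @export
record_positions <- function(record) {
  seq_len(nchar(record$sequence)) + record$numbering_offset - 1L
}

#' Residues of a record as a character vector
#' @inheritParams record_positions
#' @return Character vector of single residues.
#' @export
record_residues <- function(record) {
  strsplit(record$sequence, "")[[1]]
}

#' Extract a coordinate window of a record
#'
#' Start and end are full-length coordinates; the returned record keeps the
#' full-length numbering.
#'
#' @inheritParams record_positions
#' @param start,end 1-based inclusive full-length coordinates.
#' @param id Identifier for the extracted record (defaults to
#'   `"<id>[start-end]"`).
#' @return A [protein_record()].
#' @export
record_region <- function(record, start, end, id = NULL) {
  pos <- record_positions(record)
  if (start < min(pos) || end > max(pos) || start > end) {
    stop(sprintf("region %d-%d outside record '%s' (%d-%d)",
                 start, end, record$id, min(pos), max(pos)), call. = FALSE)
  }
  if (is.null(id)) id <- sprintf("%s[%d-%d]", record$id, start, end)
  i <- which(pos >= start & pos <= end)
  protein_record(id, paste(record_residues(record)[i], collapse = ""),
                 numbering_offset = start)
}

# ---- domain architecture ---------------------------------------------------

#' Domain partition of TDP43
#'
#' Named 1-based inclusive intervals, in full-length coordinates, for the
#' folded N-terminal domain, the two RRMs, the disordered C-terminal domain
#' (CTD) and its internal architecture: IDR1, the conserved helical region
#' (CR) and IDR2. The shipped defaults place the CTD at 267-414 with the CR
#' at 320-343; IDR1 and IDR2 are derived as the flanks of the CR within the
#' CTD. All boundaries are overridable because the precise disorder
#' boundaries are a modelling choice, not a structural fact.
#'
#' @param NTD,RRM1,RRM2,CTD,CR Length-2 integer vectors `c(start, end)`.
#' @param IDR1,IDR2 Optional explicit intervals; by default derived from
#'   `CTD` and `CR`.
#' @return Named list of intervals of class `domain_partition`.
#' @export
domain_partition <- function(NTD = c(1L, 76L), RRM1 = c(106L, 176L),
                             RRM2 = c(191L, 259L), CTD = c(267L, 414L),
                             CR = c(320L, 343L), IDR1 = NULL, IDR2 = NULL) {
  if (is.null(IDR1)) IDR1 <- c(CTD[1], CR[1] - 1L)
  if (is.null(IDR2)) IDR2 <- c(CR[2] + 1L, CTD[2])
  p <- lapply(list(NTD = NTD, RRM1 = RRM1, RRM2 = RRM2, CTD = CTD,
                   IDR1 = IDR1, CR = CR, IDR2 = IDR2),
              function(x) as.integer(x))
  for (nm in names(p)) {
    if (length(p[[nm]]) != 2L || p[[nm]][1] > p[[nm]][2]) {
      stop("invalid interval for ", nm, call. = FALSE)
    }
  }
  if (!(p$IDR1[2] < p$CR[1] && p$CR[2] < p$IDR2[1])) {
    stop("expected coordinate order IDR1 < CR < IDR2", call. = FALSE)
  }
  if (p$IDR1[1] < p$CTD[1] || p$IDR2[2] > p$CTD[2]) {
    stop("CTD must contain IDR1, CR and IDR2", call. = FALSE)
  }
  structure(p, class = "domain_partition")
}

#' The packaged human TDP43 CTD
#'
#' Residues 267-414 of human TDP43 (UniProtKB Q13148): the low-complexity
#' C-terminal domain comprising IDR1 (267-319), the conserved helical region
#' (320-343) and IDR2 (344-414). The record carries full-length numbering, so
#' familiar landmarks keep their coordinates (G309, W334, G348, G368, W385,
#' W412). The sequence ships as a FASTA fixture under `extdata`.
#'
#' @return A [protein_record()] with `numbering_offset = 267`.
#' @examples
#' ctd <- tdp43_ctd()
#' record_residues(ctd)[record_positions(ctd) == 385]  # "W"
#' @export
tdp43_ctd <- function() {
  fa <- system.file("extdata", "TDP43_CTD_human.fasta", package = "phasekit")
  x <- Biostrings::readAAStringSet(fa)
  protein_record("TDP43_CTD_human", as.character(x[[1]]),
                 numbering_offset = 267L)
}

#' Residue class scheme
#'
#' The hydrophobic class (Phi) follows the definition used throughout the
#' TDP43 sticker analysis: V, L, I, M, F, Y, W; aromatics and aliphatics are
#' its two halves, and the charged class collects K, R, E, D.
#'
#' @param hydrophobic,aromatic,aliphatic,charged Character vectors of
#'   residues; all must be subsets of the canonical alphabet.
#' @return Named list of residue sets of class `residue_classes`.
#' @export
residue_classes <- function(hydrophobic = c("V", "L", "I", "M", "F", "Y", "W"),
                            aromatic = c("F", "Y", "W"),
                            aliphatic = c("V", "L", "I", "M"),
                            charged = c("K", "R", "E", "D")) {
  cls <- list(hydrophobic = hydrophobic, aromatic = aromatic,
              aliphatic = aliphatic, charged = charged)
  for (nm in names(cls)) {
    bad <- setdiff(cls[[nm]], AA20)
    if (length(bad)) stop("class ", nm, " has non-canonical residues: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cls, class = "residue_classes")
}

#' Partition a record into its named domains
#'
#' Returns one sub-record per interval of the partition that lies fully
#' inside the record. Asking for an interval that sticks out of the record is
#' an error naming the interval, which guards against mismatched numbering.
#'
#' @param record A [protein_record()].
#' @param boundaries A [domain_partition()].
#' @param which Names of intervals to extract; defaults to every interval
#'   contained in the record.
#' @return Named list of [protein_record()] views with coordinates preserved.
#' @examples
#' views <- partition_domains(tdp43_ctd())
#' names(views)  # "CTD" "IDR1" "CR" "IDR2"
#' @export
partition_domains <- function(record, boundaries = domain_partition(),
                              which = NULL) {
  pos <- record_positions(record)
  if (is.null(which)) {
    which <- names(boundaries)[vapply(boundaries, function(iv) {
      iv[1] >= min(pos) && iv[2] <= max(pos)
    }, logical(1))]
  }
  out <- list()
  for (nm in which) {
    iv <- boundaries[[nm]]
    if (is.null(iv)) stop("unknown interval '", nm, "'", call. = FALSE)
    if (iv[1] < min(pos) || iv[2] > max(pos)) {
      stop(sprintf("interval %s (%d-%d) exceeds record '%s' (%d-%d)",
                   nm, iv[1], iv[2], record$id, min(pos), max(pos)),
           call. = FALSE)
    }
    out[[nm]] <- record_region(record, iv[1], iv[2],
                               id = paste0(record$id, "|", nm))
  }
  out
}

# ---- FASTA I/O -------------------------------------------------------------

#' Read protein records from FASTA
#'
#' @param path FASTA file.
#' @param numbering_offset Offset applied to every record (single integer or
#'   one per sequence).
#' @return List of [protein_record()] objects.
#' @export
read_protein_fasta <- function(path, numbering_offset = 1L) {
  x <- Biostrings::readAAStringSet(path)
  off <- rep_len(as.integer(numbering_offset), length(x))
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate ids in FASTA", call. = FALSE)
  out <- lapply(seq_along(x), function(i) {
    protein_record(ids[i], as.character(x[[i]]), off[i])
  })
  names(out) <- ids
  out
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
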