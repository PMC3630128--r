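# File formats: FASTA, aligned FASTA, tab-separated annotation tables.
# Biostrings does the FASTA parsing/writing; validation on top enforces the
# package's residue alphabet (20 standard letters plus X; B/Z/U rejected).

#' Read unaligned domain sequences from FASTA
#'
#' Sequence ids are taken from the header token up to the first whitespace;
#' residues are upper-cased. Gap characters are rejected (use
#' [read_alignment()] for aligned input), as are non-standard residues other
#' than `X`.
#'
#' @param path Path to a FASTA file.
#' @param domain_type `"A"` or `"AT"`.
#' @return A `data.frame` with one row per record and columns `id`,
#'   `residues`, `domain_type`, `substrate` (NA until annotated),
#'   `redundant`, `source_ref`.
#' @seealso [read_annotation()] to attach substrate labels.
#' @export
read_fasta <- function(path, domain_type = c("A", "AT")) {
  domain_type <- match.arg(domain_type)
  recs <- read_fasta_records(path)
  if (nrow(recs) == 0L) stopf("no sequences in '%s'", path)
  for (i in seq_len(nrow(recs))) {
    validate_residues(recs$seq[i], recs$id[i], allow_gaps = FALSE)
  }
  domain_sequences(recs$id, recs$seq, domain_type)
}

#' Construct a domain-sequence table
#'
#' @param id Unique sequence ids.
#' @param residues Upper-case residue strings (20 standard letters plus X).
#' @param domain_type `"A"` or `"AT"`.
#' @param substrate Optional substrate codes (NA when unknown).
#' @param redundant Logical redundancy flags.
#' @param source_ref Optional provenance strings.
#' @return A `data.frame` of domain sequences.
#' @export
domain_sequences <- function(id, residues, domain_type = c("A", "AT"),
                             substrate = NA_character_, redundant = FALSE,
                             source_ref = NA_character_) {
  domain_type <- match.arg(domain_type)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id)) {
    stopf("duplicate sequence id: '%s'", id[duplicated(id)][1L])
  }
  if (any(!nzchar(residues))) {
    stopf("zero-length sequence: '%s'", id[!nzchar(residues)][1L])
  }
  data.frame(id = id, residues = residues, domain_type = domain_type,
             substrate = substrate, redundant = redundant,
             source_ref = source_ref, stringsAsFactors = FALSE)
}

# low-level FASTA reader -> data.frame(id, seq); headers truncated at first
# whitespace; duplicate ids are a hard error.
read_fasta_records <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence id: '%s'", ids[duplicated(ids)][1L])
  }
  data.frame(id = ids, seq = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Enforce the residue alphabet. Reports the first offending position.
validate_residues <- function(seq, id, allow_gaps) {
  allowed <- c(AA20, "X", if (allow_gaps) GAP_CHARS)
  cc <- chars(seq)
  bad <- which(!(cc %in% allowed))
  if (length(bad)) {
    ch <- cc[bad[1L]]
    if (!allow_gaps && is_gap(ch)) {
      stopf("gap character in unaligned input: '%s' at position %d in '%s'",
            ch, bad[1L], id)
    }
    stopf("invalid residue '%s' at position %d in '%s'", ch, bad[1L], id)
  }
  invisible(TRUE)
}

#' Write sequences or an alignment to FASTA
#'
#' Lines wrap at 60 columns.
#'
#' @param x A domain-sequence `data.frame` (from [read_fasta()]), a
#'   `domain_msa` alignment, or a named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  v <- as_named_seqs(x)
  set <- Biostrings::BStringSet(v)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

as_named_seqs <- function(x) {
  if (inherits(x, "domain_msa")) return(x$seqs)
  if (is.data.frame(x)) return(stats::setNames(x$residues, x$id))
  if (is.character(x) && !is.null(names(x))) return(x)
  stopf("cannot interpret input as sequences")
}

#' Multiple-alignment container
#'
#' Gapped residue strings of identical length over a fixed column count.
#'
#' @param seqs Named character vector of gapped rows (gap character `-`).
#' @return An object of class `domain_msa` with elements `seqs` (named
#'   character) and `n_col`.
#' @export
new_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stopf("alignment rows must be named by sequence id")
  }
  if (anyDuplicated(names(seqs))) {
    stopf("duplicate sequence id: '%s'", names(seqs)[duplicated(names(seqs))][1L])
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- names(seqs)[lens != lens[1L]]
    stopf("ragged alignment rows (length differs from first row): %s",
          paste(off, collapse = ", "))
  }
  for (i in seq_along(seqs)) validate_residues(seqs[i], names(seqs)[i], TRUE)
  structure(list(seqs = seqs, n_col = unname(lens[1L])), class = "domain_msa")
}

#' @export
print.domain_msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x$seqs), x$n_col))
  invisible(x)
}

#' @export
as.matrix.domain_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- names(x$seqs)
  m
}

#' Number of rows / columns of an alignment
#' @param x A `domain_msa`.
#' @return Integer.
#' @export
n_rows <- function(x) length(x$seqs)

#' @rdname n_rows
#' @export
n_cols <- function(x) x$n_col

#' Read an aligned FASTA file
#'
#' All records must have equal length; ragged input is a hard error listing
#' the offending ids.
#'
#' @param path Path to aligned FASTA.
#' @return A `domain_msa`.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta_records(path)
  if (nrow(recs) == 0L) stopf("no sequences in '%s'", path)
  new_alignment(stats::setNames(recs$seq, recs$id))
}

#' @rdname read_alignment
#' @param alignment A `domain_msa` to write.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "domain_msa"))
  write_fasta(alignment, path)
}

# subset columns (and optionally rows) of an alignment
subset_alignment <- function(alignment, columns = NULL, rows = NULL) {
  m <- as.matrix(alignment)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  new_alignment(apply(m, 1L, paste, collapse = ""))
}

#' Read a substrate annotation table
#'
#' Tab-separated with header `seq_id`, `substrate`, `domain_type`,
#' `redundant`. Substrate codes are matched case-insensitively against the
#' vocabulary and canonicalized; unknown codes and duplicate ids are hard
#' errors.
#'
#' @param path Path to a TSV file.
#' @param vocabulary A [substrate_vocabulary()].
#' @return A `data.frame` with columns `seq_id`, `substrate`, `domain_type`,
#'   `redundant`.
#' @export
read_annotation <- function(path, vocabulary) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "substrate", "domain_type", "redundant")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("annotation table missing column(s): %s",
                          paste(miss, collapse = ", "))
  annotation_table(tab$seq_id, tab$substrate, tab$domain_type,
                   as.logical(tab$redundant), vocabulary)
}

#' @rdname read_annotation
#' @param seq_id,substrate,domain_type,redundant Column vectors.
#' @export
annotation_table <- function(seq_id, substrate, domain_type, redundant,
                             vocabulary) {
  seq_id <- as.character(seq_id)
  if (anyDuplicated(seq_id)) {
    stopf("duplicate seq_id in annotation: '%s'",
          seq_id[duplicated(seq_id)][1L])
  }
  substrate <- canonical_code(vocabulary, as.character(substrate))
  data.frame(seq_id = seq_id, substrate = substrate,
             domain_type = as.character(domain_type),
             redundant = as.logical(redundant), stringsAsFactors = FALSE)
}

#' @rdname read_annotation
#' @param annotation An annotation `data.frame` to write.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Join sequences and annotation, checking that every annotated id resolves.
attach_annotation <- function(sequences, annotation) {
  i <- match(sequences$id, annotation$seq_id)
  if (anyNA(i)) {
    stopf("sequence id(s) missing from annotation: %s",
          paste(sequences$id[is.na(i)], collapse = ", "))
  }
  sequences$substrate <- annotation$substrate[i]
  sequences$redundant <- annotation$redundant[i]
  sequences
}
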