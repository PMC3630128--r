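# Conservation analysis: reference-structure numbering of alignment columns,
# per-substrate 100%-identity conservation profiles, and column selections
# used to build reduced alignments. Columns where any group member carries a
# gap are never conserved (strict reading of 100% identity).

#' Map alignment columns to reference residue numbers
#'
#' The k-th non-gap column of the reference row maps to residue number k
#' (1-based), e.g. numbering AT-domain columns by the E. coli FabD
#' (PDB 1MLA) row or A-domain columns by the GrsA (PDB 1AMU) row.
#'
#' @param alignment A `domain_msa`.
#' @param reference_id Row id of the reference sequence.
#' @return Object of class `reference_numbering`: list with
#'   `reference_id`, `column_to_residue` (integer vector over all columns,
#'   NA where the reference is gapped), and `residue_to_column` (the
#'   inverse, over residues 1..ungapped length).
#' @export
build_reference_numbering <- function(alignment, reference_id) {
  stopifnot(inherits(alignment, "domain_msa"))
  if (!reference_id %in% names(alignment$seqs)) {
    stopf("reference id '%s' not present in alignment", reference_id)
  }
  row <- chars(alignment$seqs[[reference_id]])
  non_gap <- !is_gap(row)
  if (!any(non_gap)) stopf("reference row '%s' is all gaps", reference_id)
  col_to_res <- rep(NA_integer_, length(row))
  col_to_res[non_gap] <- seq_len(sum(non_gap))
  structure(
    list(reference_id = reference_id,
         column_to_residue = col_to_res,
         residue_to_column = which(non_gap)),
    class = "reference_numbering")
}

#' Columns of explicit reference residue positions
#'
#' Turns a set of reference residue numbers (e.g. the 13 AT active-site
#' positions 11, 63, 90-94, 117, 200, 201, 231, 250, 255 in FabD numbering)
#' into alignment columns.
#'
#' @param numbering A [build_reference_numbering()] result.
#' @param residue_numbers Integer residue numbers in the reference sequence.
#' @return A `residue_selection` (ascending alignment columns).
#' @export
select_reference_positions <- function(numbering, residue_numbers) {
  stopifnot(inherits(numbering, "reference_numbering"))
  bad <- residue_numbers[residue_numbers < 1 |
                         residue_numbers > length(numbering$residue_to_column)]
  if (length(bad)) {
    stopf("residue number(s) outside the reference sequence: %s",
          paste(bad, collapse = ", "))
  }
  residue_selection(sort(numbering$residue_to_column[residue_numbers]),
                    name = "explicit_reference_positions")
}

residue_selection <- function(columns, name = "selection") {
  columns <- sort(unique(as.integer(columns)))
  structure(list(name = name, columns = columns), class = "residue_selection")
}

#' @export
print.residue_selection <- function(x, ...) {
  cat(sprintf("Residue selection '%s': %d columns\n", x$name,
              length(x$columns)))
  invisible(x)
}

#' Per-group conservation profile
#'
#' A column is conserved iff every member carries the same identical
#' non-gap residue there (100% identity). For a singleton group every
#' non-gap column is conserved (vacuous universality).
#'
#' @param alignment A `domain_msa`.
#' @param members Character vector of row ids forming the group.
#' @param group Optional substrate code recorded on the profile.
#' @return Object of class `conservation_profile`: list with `group`,
#'   `conserved_columns` (integer), `consensus` (named character,
#'   names = columns).
#' @export
conservation_profile <- function(alignment, members, group = NA_character_) {
  stopifnot(inherits(alignment, "domain_msa"))
  miss <- setdiff(members, names(alignment$seqs))
  if (length(miss)) stopf("member id(s) not in alignment: %s",
                          paste(miss, collapse = ", "))
  if (length(members) == 0L) stopf("empty member set")
  m <- as.matrix(alignment)[members, , drop = FALSE]
  cons <- apply(m, 2L, function(col) {
    u <- unique(col)
    if (length(u) == 1L && !is_gap(u)) u else NA_character_
  })
  keep <- which(!is.na(cons))
  structure(
    list(group = group, conserved_columns = keep,
         consensus = stats::setNames(cons[keep], keep)),
    class = "conservation_profile")
}

#' Select columns conserved across substrate groups
#'
#' Selects the columns conserved in at least `k` of the supplied group
#' profiles. With `exclude_global = TRUE`, columns conserved in *all*
#' profiles with one common consensus residue are removed; such globally
#' invariant columns carry no substrate information. (The looser reading --
#' conserved in each group but with different residues -- is deliberately
#' not treated as global: those columns are discriminative.)
#'
#' @param profiles List of [conservation_profile()] results.
#' @param k Minimum number of profiles a column must be conserved in
#'   (default 1, i.e. conserved in any group).
#' @param exclude_global Drop globally conserved columns (default FALSE).
#' @param name Name recorded on the selection.
#' @return A `residue_selection`.
#' @export
select_columns <- function(profiles, k = 1L, exclude_global = FALSE,
                           name = NULL) {
  if (length(profiles) < 1L) stopf("need at least one profile")
  if (k < 1L || k > length(profiles)) {
    stopf("k must be between 1 and the number of profiles")
  }
  counts <- table(unlist(lapply(profiles, `[[`, "conserved_columns")))
  selected <- as.integer(names(counts))[counts >= k]
  if (exclude_global) {
    global <- globally_conserved(profiles)
    selected <- setdiff(selected, global)
  }
  if (is.null(name)) {
    name <- sprintf("conserved_min_%d_groups%s", k,
                    if (exclude_global) "_excl_global" else "")
  }
  residue_selection(selected, name = name)
}

# columns conserved in every profile with an identical consensus residue
globally_conserved <- function(profiles) {
  common <- Reduce(intersect, lapply(profiles, `[[`, "conserved_columns"))
  if (!length(common)) return(integer(0))
  keep <- vapply(common, function(col) {
    res <- vapply(profiles, function(p) p$consensus[[as.character(col)]], "")
    length(unique(res)) == 1L
  }, logical(1))
  common[keep]
}

#' Extract a reduced alignment from selected columns
#'
#' @param alignment A `domain_msa`.
#' @param selection A `residue_selection` or integer column vector.
#' @return A `domain_msa` over the selected columns, row order preserved.
#' @export
extract_reduced <- function(alignment, selection) {
  cols <- if (inherits(selection, "residue_selection")) {
    selection$columns
  } else {
    sort(unique(as.integer(selection)))
  }
  if (!length(cols)) stopf("empty column selection")
  if (any(cols < 1L | cols > n_cols(alignment))) {
    stopf("selected column outside the alignment")
  }
  subset_alignment(alignment, columns = cols)
}

#' Position-frequency matrix of an alignment
#'
#' Plain-text alternative to a sequence logo: per-column counts of each
#' residue (gaps and X excluded).
#'
#' @param alignment A `domain_msa`.
#' @param members Optional row subset.
#' @return 20 x n_col integer matrix, rows in [aa_alphabet()] order.
#' @export
position_frequency_matrix <- function(alignment, members = NULL) {
  m <- as.matrix(alignment)
  if (!is.null(members)) m <- m[members, , drop = FALSE]
  apply(m, 2L, function(col) {
    tab <- table(factor(col, levels = AA20))
    as.integer(tab)
  }) -> out
  rownames(out) <- AA20
  out
}
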