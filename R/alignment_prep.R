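# Alignment preparation: iterative removal of terminal extensions so that
# neither gaps nor overhanging residues remain at the alignment ends, and
# greedy removal of (near-)duplicate sequences. Homogeneous terminal columns
# make per-substrate models comparable; redundancy removal balances the
# coverage of sequence space.

#' Terminal overhang of an alignment
#'
#' The leading overhang is the largest `c` such that columns `1..c` each
#' contain at least one gap; the trailing overhang is defined symmetrically
#' from the last column. Both are 0 exactly when the first and last columns
#' are gap-free.
#'
#' @param alignment A `domain_msa`.
#' @return Integer vector `c(leading, trailing)`.
#' @examples
#' a <- new_alignment(c(x = "--KLA", y = "MAKL-"))
#' terminal_overhang(a)  # c(2, 1)
#' @export
terminal_overhang <- function(alignment) {
  stopifnot(inherits(alignment, "domain_msa"))
  m <- as.matrix(alignment)
  has_gap <- apply(m, 2L, function(col) any(is_gap(col)))
  leading <- 0L
  while (leading < length(has_gap) && has_gap[leading + 1L]) {
    leading <- leading + 1L
  }
  trailing <- 0L
  while (trailing < length(has_gap) &&
         has_gap[length(has_gap) - trailing]) {
    trailing <- trailing + 1L
  }
  c(leading = leading, trailing = trailing)
}

#' Iteratively trim terminal extensions
#'
#' Aligns the sequences, removes from every row the residues that fall in
#' the leading/trailing overhang columns (rows without extensions lose
#' nothing), and re-aligns, repeating until the overhang is `(0, 0)` or
#' `max_rounds` is reached. The number of residues removed per sequence and
#' a convergence flag are attached to the result.
#'
#' @param sequences A domain-sequence `data.frame` or named character vector
#'   of unaligned residues.
#' @param realigner A realigner function (see [identity_realigner()],
#'   [scripted_realigner()], [mafft_realigner()]): maps unaligned sequences
#'   to a `domain_msa` over exactly those ids.
#' @param max_rounds Maximum align/trim iterations (default 10). Exceeding
#'   it sets `attr(result, "converged") = FALSE` with a warning rather than
#'   raising an error.
#' @param verbose Log one line per round (round, leading, trailing, columns).
#' @return The final `domain_msa` with attributes `removed` (named integer,
#'   residues removed per id), `rounds`, `converged`.
#' @export
trim_terminal_extensions <- function(sequences, realigner, max_rounds = 10L,
                                     verbose = FALSE) {
  seqs <- as_named_seqs(sequences)
  seqs <- vapply(seqs, ungap, "", USE.NAMES = TRUE)
  if (length(seqs) < 2L) stopf("need at least 2 sequences to trim")
  original_len <- nchar(seqs)
  aln <- check_realigned(realigner(seqs), seqs)
  rounds <- 0L
  converged <- TRUE
  repeat {
    oh <- terminal_overhang(aln)
    if (verbose) {
      message(sprintf("trim round %d: leading=%d trailing=%d columns=%d",
                      rounds, oh[1L], oh[2L], n_cols(aln)))
    }
    if (sum(oh) == 0L) break
    if (rounds >= max_rounds) {
      warnf("terminal trimming did not converge in %d rounds", max_rounds)
      converged <- FALSE
      break
    }
    if (oh[1L] + oh[2L] >= n_cols(aln)) {
      stopf("trimming would remove every column")
    }
    keep <- seq.int(oh[1L] + 1L, n_cols(aln) - oh[2L])
    inner <- subset_alignment(aln, columns = keep)
    seqs <- vapply(inner$seqs, ungap, "", USE.NAMES = TRUE)
    empty <- names(seqs)[!nzchar(seqs)]
    if (length(empty)) {
      stopf("sequence trimmed to length 0: %s", paste(empty, collapse = ", "))
    }
    aln <- check_realigned(realigner(seqs), seqs)
    rounds <- rounds + 1L
  }
  removed <- original_len - nchar(vapply(aln$seqs, ungap, ""))
  structure(aln, removed = removed, rounds = rounds, converged = converged)
}

# Realigner contract check: exactly the input ids, ungapped rows equal input.
check_realigned <- function(alignment, seqs) {
  if (!inherits(alignment, "domain_msa")) {
    stopf("realigner must return a domain_msa")
  }
  if (!setequal(names(alignment$seqs), names(seqs))) {
    stopf("realigner changed the sequence id set")
  }
  got <- vapply(alignment$seqs[names(seqs)], ungap, "")
  if (!identical(unname(got), unname(seqs))) {
    bad <- names(seqs)[got != seqs][1L]
    stopf("realigner altered residues of '%s'", bad)
  }
  alignment
}

#' Built-in realigners
#'
#' `identity_realigner()` stacks equal-length sequences without inserting
#' gaps (errors on unequal lengths) -- the fixed point of trimming for
#' gap-free alignments. `scripted_realigner()` replays a fixed list of
#' alignments on successive calls, checking the realigner contract each
#' time; it makes the trimming loop testable without any external program.
#' `mafft_realigner()` shells out to MAFFT.
#'
#' @return A function mapping a named character vector of unaligned
#'   sequences to a `domain_msa`.
#' @export
identity_realigner <- function() {
  function(seqs) {
    if (length(unique(nchar(seqs))) != 1L) {
      stopf("identity realigner requires equal-length sequences")
    }
    new_alignment(seqs)
  }
}

#' @rdname identity_realigner
#' @param alignments List of `domain_msa` objects returned on calls
#'   1, 2, ...; the last entry is reused if called more often.
#' @export
scripted_realigner <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  call_n <- 0L
  function(seqs) {
    call_n <<- call_n + 1L
    alignments[[min(call_n, length(alignments))]]
  }
}

#' @rdname identity_realigner
#' @param exe Path to the mafft executable.
#' @param args Extra command-line arguments.
#' @export
mafft_realigner <- function(exe = "mafft", args = c("--auto", "--quiet")) {
  force(exe); force(args)
  function(seqs) {
    fin <- tempfile(fileext = ".fasta")
    fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    write_fasta(seqs, fin)
    status <- system2(exe, c(args, shQuote(fin)), stdout = fout)
    if (status != 0L) stopf("%s exited with status %d", exe, status)
    read_alignment(fout)
  }
}

#' Remove (near-)duplicate sequences
#'
#' Greedy single-linkage in input order: a sequence is removed when its
#' global pairwise identity to an already-kept sequence *of the same
#' substrate* reaches the threshold. Identity is the number of matching
#' positions divided by the number of aligned columns of a global pairwise
#' alignment (a pairwise alignment has no double-gap columns). Sequences
#' with different substrate labels are never collapsed.
#'
#' @param sequences Domain-sequence `data.frame` with `substrate` filled in
#'   (NA substrates are compared only against other NA-substrate entries).
#' @param identity_threshold Fraction in (0.5, 1]; default 0.98.
#' @return List with `kept` (data.frame) and `removed` (data.frame with
#'   columns `removed_id`, `kept_id`, `identity`).
#' @export
deduplicate <- function(sequences, identity_threshold = 0.98) {
  stopifnot(is.data.frame(sequences))
  if (identity_threshold <= 0.5 || identity_threshold > 1) {
    stopf("identity_threshold must be in (0.5, 1]")
  }
  kept <- integer(0)
  removed <- data.frame(removed_id = character(0), kept_id = character(0),
                        identity = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sequences))) {
    sub_i <- sequences$substrate[i]
    hit <- NA_integer_
    hit_id <- NA_real_
    for (j in kept) {
      sub_j <- sequences$substrate[j]
      same_sub <- (is.na(sub_i) && is.na(sub_j)) ||
        (!is.na(sub_i) && !is.na(sub_j) && sub_i == sub_j)
      if (!same_sub) next
      idy <- pairwise_identity(sequences$residues[i], sequences$residues[j])
      if (idy >= identity_threshold) {
        hit <- j
        hit_id <- idy
        break
      }
    }
    if (is.na(hit)) {
      kept <- c(kept, i)
    } else {
      removed <- rbind(removed, data.frame(
        removed_id = sequences$id[i], kept_id = sequences$id[hit],
        identity = hit_id, stringsAsFactors = FALSE))
    }
  }
  list(kept = sequences[kept, , drop = FALSE], removed = removed)
}

#' Global pairwise identity
#'
#' Needleman-Wunsch alignment with simple identity scoring (match +2,
#' mismatch -1, gap open 4, gap extend 1); identity = matches / aligned
#' columns.
#'
#' @param a,b Residue strings.
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (identical(a, b)) return(1.0)
  mat <- identity_submat()
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

identity_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ab <- c(AA20, "X")
      m <- matrix(-1, length(ab), length(ab), dimnames = list(ab, ab))
      diag(m) <- 2
      m["X", ] <- 0
      m[, "X"] <- 0
      cache <<- m
    }
    cache
  }
})
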