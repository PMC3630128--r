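# Profile hidden Markov models over the plain match/insert/delete
# architecture, trained from an aligned substrate (sub)group and scored by
# global Viterbi in log-odds bits. I->D and D->I moves are fixed to
# probability 0 (common profile practice); alignment is global because
# queries are pre-excised domain sequences.
#
# State layout for a model with M match states:
#   begin = node 0; match states M_1..M_M; insert states I_0..I_M;
#   delete states D_1..D_M; end reached from node M.
# Transitions are stored per node k = 0..M as the probabilities of the
# moves out of that node's states into node k+1 (node M -> end):
#   mm, mi, md  out of M_k (begin acts as M_0); md undefined at node M
#   im, ii      out of I_k
#   dm, dd      out of D_k (undefined at node 0; dd undefined at node M)

#' Flag match columns of an aligned group
#'
#' A column is a match column iff its gap fraction is at most one half
#' (ties count as match); the remaining columns are insert columns.
#'
#' @param alignment A `domain_msa` (the aligned training subset).
#' @return Logical vector over columns; at least one TRUE or an error.
#' @export
assign_match_columns <- function(alignment) {
  stopifnot(inherits(alignment, "domain_msa"))
  m <- as.matrix(alignment)
  gap_frac <- colMeans(matrix(is_gap(m), nrow = nrow(m)))
  flags <- gap_frac <= 0.5
  if (!any(flags)) stopf("no match columns (all columns mostly gaps)")
  flags
}

#' Train a profile HMM from an aligned group
#'
#' Match emissions are per-column residue counts plus
#' `pseudocount * background`, normalized. Transition probabilities are
#' counted from each row's state path through the match/insert/delete
#' skeleton, smoothed by adding `pseudocount` to every legal move, and
#' normalized per state. Insert emissions default to the background
#' distribution. Residue `X` is skipped when counting emissions.
#'
#' @param alignment A `domain_msa` of the training (sub)group.
#' @param name Model name (unique within a library).
#' @param substrate Substrate code the model predicts.
#' @param subgroup Integer subgroup index (0 for single models).
#' @param pseudocount Smoothing weight (default 1; 0 gives pure maximum
#'   likelihood, which can assign probability 0 and hence -Inf log-odds).
#' @param background Named vector of 20 background frequencies (default
#'   uniform 1/20).
#' @param match_flags Optional precomputed [assign_match_columns()] result.
#' @return An object of class `profile_hmm`.
#' @export
build_profile_hmm <- function(alignment, name, substrate,
                              subgroup = 0L, pseudocount = 1,
                              background = NULL, match_flags = NULL) {
  stopifnot(inherits(alignment, "domain_msa"))
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  background <- check_background(background)
  if (is.null(match_flags)) match_flags <- assign_match_columns(alignment)
  if (length(match_flags) != n_cols(alignment)) {
    stopf("match_flags length must equal the column count")
  }
  M <- sum(match_flags)
  mat <- as.matrix(alignment)
  n_seq <- nrow(mat)

  # --- emissions -----------------------------------------------------------
  match_cols <- which(match_flags)
  emis_counts <- matrix(0, nrow = M, ncol = 20L,
                        dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    col <- mat[, match_cols[k]]
    col <- col[col %in% AA20]
    if (length(col)) {
      tb <- table(factor(col, levels = AA20))
      emis_counts[k, ] <- as.numeric(tb)
    }
  }
  match_em <- emis_counts + pseudocount * matrix(background, M, 20L,
                                                byrow = TRUE)
  rs <- rowSums(match_em)
  zero <- rs == 0
  if (any(zero)) {  # pseudocount 0 and an all-gap/X match column
    match_em[zero, ] <- 1 / 20
    rs[zero] <- 1
  }
  match_em <- match_em / rs
  insert_em <- matrix(background, M + 1L, 20L, byrow = TRUE,
                      dimnames = list(NULL, AA20))

  # --- transitions ---------------------------------------------------------
  # node index of each column: match columns are nodes 1..M; an insert
  # column belongs to the node of the preceding match column
  node_of_col <- cumsum(match_flags)
  tc <- transition_counts(mat, match_flags, node_of_col, M)
  trans <- normalize_transitions(tc, M, pseudocount)

  structure(
    list(name = name, substrate = substrate, subgroup = as.integer(subgroup),
         M = M, alphabet = AA20, background = background,
         match_emissions = match_em, insert_emissions = insert_em,
         transitions = trans, n_train = n_seq),
    class = "profile_hmm")
}

check_background <- function(background) {
  if (is.null(background)) {
    return(stats::setNames(rep(1 / 20, 20L), AA20))
  }
  if (length(background) != 20L) stopf("background must have 20 entries")
  if (!is.null(names(background))) background <- background[AA20]
  if (anyNA(background) || any(background <= 0)) {
    stopf("background frequencies must be positive for all 20 residues")
  }
  stats::setNames(as.numeric(background) / sum(background), AA20)
}

# Count the 7 legal moves along every row's state path. Matrix rows are
# nodes 0..M, columns mm, mi, md, im, ii, dm, dd. The architecture fixes
# D->I and I->D to probability 0; training rows that pair a deletion with
# an adjacent insertion would require those moves, and such events are
# simply not counted (smoothing covers the states involved).
transition_counts <- function(mat, match_flags, node_of_col, M) {
  moves <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  tc <- matrix(0, nrow = M + 1L, ncol = 7L, dimnames = list(NULL, moves))
  bump <- function(nd, key) {
    if (key %in% moves) tc[nd + 1L, key] <<- tc[nd + 1L, key] + 1
  }
  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    state <- "m"; node <- 0L  # begin
    for (j in seq_along(row)) {
      gap <- is_gap(row[j])
      if (match_flags[j]) {
        to <- if (gap) "d" else "m"
        bump(node, paste0(state, to))
        state <- to; node <- node_of_col[j]
      } else if (!gap) {
        bump(node, paste0(state, "i"))
        state <- "i"
      }
    }
    # exit to end (recorded as the "to match" move at node M)
    bump(M, paste0(state, "m"))
  }
  tc
}

# Laplace-smooth and normalize per state, honouring which moves exist at
# which node. States never visited at pseudocount 0 fall back to uniform
# over their legal moves so the sum-to-1 invariant always holds.
normalize_transitions <- function(tc, M, pseudocount) {
  trans <- matrix(0, nrow = M + 1L, ncol = 7L,
                  dimnames = list(NULL, colnames(tc)))
  for (nd in 0:M) {
    m_moves <- if (nd < M) c("mm", "mi", "md") else c("mm", "mi")
    i_moves <- c("im", "ii")
    d_moves <- if (nd == 0L) character(0)
               else if (nd < M) c("dm", "dd") else "dm"
    for (mv in list(m_moves, i_moves, d_moves)) {
      if (!length(mv)) next
      cnt <- tc[nd + 1L, mv] + pseudocount
      tot <- sum(cnt)
      trans[nd + 1L, mv] <- if (tot > 0) cnt / tot else 1 / length(mv)
    }
  }
  trans
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s' (substrate %s%s): %d match states, %d training seq(s)\n",
              x$name, x$substrate,
              if (x$subgroup > 0L) sprintf(", subgroup %d", x$subgroup) else "",
              x$M, x$n_train))
  invisible(x)
}

# residue -> log2 odds lookup for one emission matrix; X scores 0
emission_log_odds <- function(em, background) {
  lo <- log2(sweep(em, 2L, background, `/`))
  cbind(lo, X = 0)
}

#' Score a sequence against a profile HMM
#'
#' Global Viterbi over the match/insert/delete architecture, maximizing the
#' summed log-odds (emission `log2(p / background)` plus transition
#' `log2 p`). Residue `X` contributes zero log-odds in any emitting state.
#' The bit score is the log2-odds of the best path versus the background
#' (null) model; `raw_log_odds` is the same quantity in nats.
#'
#' @param hmm A `profile_hmm`.
#' @param sequence A residue string, a single-row domain-sequence
#'   `data.frame`, or a named length-1 character vector.
#' @return Object of class `hmm_score`: list with `model_name`, `substrate`,
#'   `bit_score`, `raw_log_odds`, `path_length` (number of states on the
#'   best path, excluding begin/end).
#' @export
viterbi_bits <- function(hmm, sequence) {
  stopifnot(inherits(hmm, "profile_hmm"))
  seq <- single_sequence(sequence)
  x <- chars(seq)
  L <- length(x)
  if (L == 0L) stopf("empty sequence")
  bad <- which(!(x %in% c(AA20, "X")))
  if (length(bad)) stopf("invalid residue '%s' at position %d", x[bad[1L]], bad[1L])
  em_m <- emission_log_odds(hmm$match_emissions, hmm$background)
  em_i <- emission_log_odds(hmm$insert_emissions, hmm$background)
  tr <- log2(hmm$transitions)  # illegal moves are 0 -> -Inf, never selected
  xi <- match(x, colnames(em_m))
  res <- .viterbi_core(em_m, em_i, tr, xi)
  # -Inf score means no positive-probability path exists (possible at
  # pseudocount 0), in which case there is no path length
  structure(
    list(model_name = hmm$name, substrate = hmm$substrate,
         bit_score = res$score, raw_log_odds = res$score * log(2),
         path_length = res$path_length),
    class = "hmm_score")
}

#' @export
print.hmm_score <- function(x, ...) {
  cat(sprintf("%s (%s): %.3f bits, path length %d\n", x$model_name,
              x$substrate, x$bit_score, x$path_length))
  invisible(x)
}

single_sequence <- function(sequence) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    return(toupper(sequence$residues))
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  toupper(unname(sequence))
}

#' Score one sequence against every model of a library
#'
#' @param library A `substrate_hmm` model library.
#' @param sequence A residue string or single-row domain-sequence data.frame.
#' @return `data.frame` with one row per model (`model`, `substrate`,
#'   `bits`, `path_length`), sorted by descending bit score; ties broken by
#'   model name.
#' @export
score_all <- function(library, sequence) {
  stopifnot(inherits(library, "substrate_hmm"))
  if (!length(library$models)) stopf("empty model library")
  res <- lapply(library$models, viterbi_bits, sequence = sequence)
  out <- data.frame(
    model = vapply(res, `[[`, "", "model_name"),
    substrate = vapply(res, `[[`, "", "substrate"),
    bits = vapply(res, `[[`, 0, "bit_score"),
    path_length = vapply(res, `[[`, 0L, "path_length"),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$bits, out$model), , drop = FALSE]
}
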