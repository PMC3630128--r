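# Model libraries and thresholded classification. `substrate_hmm()` is the
# fitting front end: it takes the trimmed training alignment plus substrate
# annotation and returns a classed library of profile HMMs -- one model per
# substrate ("single") or, for well-represented substrates, one model per
# NJ-tree clade ("ensemble"). `predict()` classifies unaligned queries by
# the best-scoring model, flagged unreliable below the bit-score threshold.

default_threshold <- function(domain_type) {
  switch(domain_type, AT = 325, A = 625)
}

default_size_threshold <- function(domain_type) {
  switch(domain_type, AT = 10L, A = 15L)
}

#' Fit a substrate-specific profile-HMM classifier
#'
#' Builds one profile HMM per substrate from the aligned training rows
#' (`mode = "single"`), or an ensemble with 2-4 clade-specific models per
#' substrate that has at least `size_threshold` members
#' (`mode = "ensemble"`). Substrates with a single training sequence are
#' excluded (no reliable model can be made) and reported in the fit.
#' Ensemble partitions default to [substrate_subgroups()] on the NJ tree of
#' the training alignment; explicit partitions can be supplied to reproduce
#' a published subdivision.
#'
#' @param alignment A `domain_msa` of all training sequences (typically the
#'   output of [trim_terminal_extensions()], possibly column-reduced via
#'   [extract_reduced()]).
#' @param annotation Annotation `data.frame` (`seq_id`, `substrate`)
#'   covering every alignment row.
#' @param mode `"single"` or `"ensemble"`.
#' @param domain_type `"A"` or `"AT"`; sets the default bit-score threshold
#'   (625 / 325) and ensemble size threshold (15 / 10).
#' @param threshold_bits Reliability threshold in bits; predictions scoring
#'   below it are flagged unreliable.
#' @param size_threshold Minimum group size for ensemble subdivision.
#' @param partitions Optional named list of [substrate_subgroups()] results
#'   (or plain lists of id vectors) keyed by substrate code.
#' @param max_parts,min_part_size Passed to [substrate_subgroups()] when
#'   partitions are derived automatically.
#' @param pseudocount,background Passed to [build_profile_hmm()].
#' @return An object of class `substrate_hmm` with components `models`
#'   (named list of `profile_hmm`), `groups` (training ids per model),
#'   `threshold_bits`, `mode`, `domain_type`, `excluded` (singleton
#'   substrates), and the training alignment.
#' @seealso [predict.substrate_hmm()], [evaluate_library()],
#'   [loo_cross_validate()]
#' @export
substrate_hmm <- function(alignment, annotation,
                          mode = c("single", "ensemble"),
                          domain_type = c("A", "AT"),
                          threshold_bits = NULL, size_threshold = NULL,
                          partitions = NULL, max_parts = 4L,
                          min_part_size = 3L, pseudocount = 1,
                          background = NULL) {
  mode <- match.arg(mode)
  domain_type <- match.arg(domain_type)
  if (is.null(threshold_bits)) threshold_bits <- default_threshold(domain_type)
  if (is.null(size_threshold)) {
    size_threshold <- default_size_threshold(domain_type)
  }
  groups <- resolve_groups(split_groups(alignment, annotation), alignment)
  if (mode == "single") {
    fit <- build_single_library(groups, domain_type,
                                threshold_bits = threshold_bits,
                                pseudocount = pseudocount,
                                background = background)
  } else {
    if (is.null(partitions)) {
      partitions <- auto_partitions(alignment, annotation, groups,
                                    size_threshold, max_parts, min_part_size)
    }
    fit <- build_ensemble_library(groups, domain_type, partitions,
                                  size_threshold = size_threshold,
                                  threshold_bits = threshold_bits,
                                  pseudocount = pseudocount,
                                  background = background)
  }
  fit$alignment <- alignment
  fit$call <- match.call()
  fit
}

# named list: substrate -> character vector of member ids (alignment rows)
split_groups <- function(alignment, annotation) {
  ids <- names(alignment$seqs)
  i <- match(ids, annotation$seq_id)
  if (anyNA(i)) {
    stopf("alignment row(s) missing from annotation: %s",
          paste(ids[is.na(i)], collapse = ", "))
  }
  split(ids, annotation$substrate[i])
}

auto_partitions <- function(alignment, annotation, groups, size_threshold,
                            max_parts, min_part_size) {
  big <- names(groups)[lengths(groups) >= size_threshold]
  if (!length(big)) return(list())
  tree <- nj_tree(alignment)
  parts <- lapply(big, function(s) {
    substrate_subgroups(tree, annotation, s, max_parts = max_parts,
                        min_part_size = min_part_size)
  })
  stats::setNames(parts, big)
}

#' Build a single-model library
#'
#' One profile HMM per substrate with at least two member sequences;
#' singleton substrates are excluded and listed in `$excluded`.
#'
#' @param groups Named list mapping substrate code to the ids of its
#'   training rows; every id must be a row of `alignment` (groups as
#'   produced internally by [substrate_hmm()]), together with an
#'   `alignment` attribute, or supply `alignment` via the `...` of
#'   [substrate_hmm()]. Most users call [substrate_hmm()] instead.
#' @param domain_type `"A"` or `"AT"`.
#' @param threshold_bits,pseudocount,background See [substrate_hmm()].
#' @param alignment The full training `domain_msa` (defaults to the
#'   alignment attached to `groups`).
#' @return A `substrate_hmm` library (without training-alignment attached).
#' @keywords internal
#' @export
build_single_library <- function(groups, domain_type, threshold_bits = NULL,
                                 pseudocount = 1, background = NULL,
                                 alignment = attr(groups, "alignment")) {
  groups <- resolve_groups(groups, alignment)
  alignment <- attr(groups, "alignment")
  if (is.null(threshold_bits)) threshold_bits <- default_threshold(domain_type)
  sizes <- lengths(groups)
  qualifying <- names(groups)[sizes >= 2L]
  excluded <- data.frame(substrate = names(groups)[sizes < 2L],
                         n = unname(sizes[sizes < 2L]),
                         stringsAsFactors = FALSE)
  if (!length(qualifying)) stopf("no substrate has >= 2 sequences")
  models <- list()
  members <- list()
  for (s in sort(qualifying)) {
    sub_aln <- subset_alignment(alignment, rows = groups[[s]])
    models[[s]] <- build_profile_hmm(sub_aln, name = s, substrate = s,
                                     subgroup = 0L,
                                     pseudocount = pseudocount,
                                     background = background)
    members[[s]] <- groups[[s]]
  }
  new_library(models, members, domain_type, "single", threshold_bits,
              excluded, pseudocount, background)
}

#' Build an ensemble library
#'
#' Substrates at or above `size_threshold` that come with a multi-part
#' partition get one model per part (named `substrate_1`, `substrate_2`,
#' ...); every other substrate falls back to its single model, so the
#' ensemble always has at least as many models as the single library.
#'
#' @inheritParams build_single_library
#' @param partitions Named list (by substrate) of `clade_partition` objects
#'   or plain lists of id vectors.
#' @param size_threshold Minimum group size for subdivision.
#' @keywords internal
#' @export
build_ensemble_library <- function(groups, domain_type, partitions,
                                   size_threshold = NULL,
                                   threshold_bits = NULL, pseudocount = 1,
                                   background = NULL,
                                   alignment = attr(groups, "alignment")) {
  groups <- resolve_groups(groups, alignment)
  alignment <- attr(groups, "alignment")
  if (is.null(threshold_bits)) threshold_bits <- default_threshold(domain_type)
  if (is.null(size_threshold)) {
    size_threshold <- default_size_threshold(domain_type)
  }
  sizes <- lengths(groups)
  qualifying <- names(groups)[sizes >= 2L]
  excluded <- data.frame(substrate = names(groups)[sizes < 2L],
                         n = unname(sizes[sizes < 2L]),
                         stringsAsFactors = FALSE)
  if (!length(qualifying)) stopf("no substrate has >= 2 sequences")
  models <- list()
  members <- list()
  for (s in sort(qualifying)) {
    parts <- partition_parts(partitions[[s]])
    use_ensemble <- sizes[[s]] >= size_threshold && length(parts) >= 2L
    if (use_ensemble) {
      bad <- setdiff(unlist(parts), groups[[s]])
      if (length(bad)) {
        stopf("partition for '%s' references unknown id(s): %s", s,
              paste(bad, collapse = ", "))
      }
      if (!setequal(unlist(parts), groups[[s]])) {
        stopf("partition for '%s' does not cover the group", s)
      }
      for (p in seq_along(parts)) {
        nm <- sprintf("%s_%d", s, p)
        sub_aln <- subset_alignment(alignment, rows = parts[[p]])
        models[[nm]] <- build_profile_hmm(sub_aln, name = nm, substrate = s,
                                          subgroup = p,
                                          pseudocount = pseudocount,
                                          background = background)
        members[[nm]] <- parts[[p]]
      }
    } else {
      sub_aln <- subset_alignment(alignment, rows = groups[[s]])
      models[[s]] <- build_profile_hmm(sub_aln, name = s, substrate = s,
                                       subgroup = 0L,
                                       pseudocount = pseudocount,
                                       background = background)
      members[[s]] <- groups[[s]]
    }
  }
  new_library(models, members, domain_type, "ensemble", threshold_bits,
              excluded, pseudocount, background)
}

partition_parts <- function(p) {
  if (is.null(p)) return(list())
  if (inherits(p, "clade_partition")) return(p$subgroups)
  if (is.list(p)) return(p)
  stopf("partition must be a clade_partition or list of id vectors")
}

resolve_groups <- function(groups, alignment) {
  if (is.null(alignment)) {
    stopf("an alignment must accompany the groups")
  }
  stopifnot(inherits(alignment, "domain_msa"))
  miss <- setdiff(unlist(groups), names(alignment$seqs))
  if (length(miss)) stopf("group id(s) not in alignment: %s",
                          paste(miss, collapse = ", "))
  attr(groups, "alignment") <- alignment
  groups
}

new_library <- function(models, members, domain_type, mode, threshold_bits,
                        excluded, pseudocount, background) {
  if (anyDuplicated(names(models))) {
    stopf("duplicate model name: '%s'",
          names(models)[duplicated(names(models))][1L])
  }
  structure(
    list(domain_type = domain_type, mode = mode, models = models,
         groups = members, threshold_bits = threshold_bits,
         excluded = excluded, pseudocount = pseudocount,
         background = check_background(background)),
    class = "substrate_hmm")
}

#' @export
print.substrate_hmm <- function(x, ...) {
  cat(sprintf("Substrate-specific profile-HMM library (%s domains, %s mode)\n",
              x$domain_type, x$mode))
  cat(sprintf("  models: %d over %d substrate(s); threshold %.1f bits\n",
              length(x$models),
              length(unique(vapply(x$models, `[[`, "", "substrate"))),
              x$threshold_bits))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded singleton substrate(s): %s\n",
                paste(x$excluded$substrate, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.substrate_hmm <- function(object, ...) {
  subs <- vapply(object$models, `[[`, "", "substrate")
  tab <- data.frame(
    model = names(object$models),
    substrate = unname(subs),
    subgroup = vapply(object$models, `[[`, 0L, "subgroup"),
    match_states = vapply(object$models, `[[`, 0L, "M"),
    n_train = vapply(object$models, `[[`, 0L, "n_train"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(library = object, models = tab),
            class = "summary.substrate_hmm")
}

#' @export
print.summary.substrate_hmm <- function(x, ...) {
  print(x$library)
  print(x$models, row.names = FALSE)
  invisible(x)
}

#' Classify query sequences
#'
#' Each query is scored against every model; the best bit score decides the
#' predicted substrate (ties broken by model name). Predictions scoring
#' below the library threshold are flagged `reliable = FALSE`. The
#' runner-up model is reported for diagnostics.
#'
#' @param object A fitted `substrate_hmm` library.
#' @param sequences A domain-sequence `data.frame` (e.g. from
#'   [read_fasta()]), a named character vector of residue strings, or a
#'   single string.
#' @param threshold_bits Optional threshold override.
#' @param ... Unused.
#' @return `data.frame` with columns `seq_id`, `substrate`, `model`,
#'   `bits`, `reliable`, `runner_up_model`, `runner_up_bits`.
#' @export
predict.substrate_hmm <- function(object, sequences,
                                  threshold_bits = object$threshold_bits,
                                  ...) {
  seqs <- query_seqs(sequences)
  rows <- lapply(seq_along(seqs), function(i) {
    sc <- score_all(object, seqs[[i]])
    data.frame(
      seq_id = names(seqs)[i],
      substrate = sc$substrate[1L],
      model = sc$model[1L],
      bits = sc$bits[1L],
      reliable = sc$bits[1L] >= threshold_bits,
      runner_up_model = if (nrow(sc) > 1L) sc$model[2L] else NA_character_,
      runner_up_bits = if (nrow(sc) > 1L) sc$bits[2L] else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

query_seqs <- function(sequences) {
  if (is.data.frame(sequences)) {
    return(stats::setNames(as.list(toupper(sequences$residues)),
                           sequences$id))
  }
  if (is.character(sequences)) {
    nm <- names(sequences)
    if (is.null(nm)) nm <- paste0("query", seq_along(sequences))
    return(stats::setNames(as.list(toupper(unname(sequences))), nm))
  }
  stopf("cannot interpret query sequences")
}

#' Simulate sequences from a fitted model
#'
#' Draws emission paths from one profile HMM of the library -- useful for
#' eyeballing what a model has learned.
#'
#' @param object A `substrate_hmm`.
#' @param nsim Number of sequences.
#' @param seed Integer seed.
#' @param model Model name (default: first model).
#' @param ... Unused.
#' @return Named character vector of simulated residue strings.
#' @export
simulate.substrate_hmm <- function(object, nsim = 1, seed = 1,
                                   model = names(object$models)[1L], ...) {
  hmm <- object$models[[model]]
  if (is.null(hmm)) stopf("no model named '%s'", model)
  with_seed(seed, {
    out <- vapply(seq_len(nsim), function(i) sample_path(hmm), "")
  })
  stats::setNames(out, sprintf("%s_sim%d", model, seq_len(nsim)))
}

sample_path <- function(hmm) {
  res <- character(0)
  state <- "m"; node <- 0L
  tr <- hmm$transitions
  repeat {
    moves <- switch(state,
      m = c(m = tr[node + 1L, "mm"], i = tr[node + 1L, "mi"],
            d = if (node < hmm$M) tr[node + 1L, "md"] else 0),
      i = c(m = tr[node + 1L, "im"], i = tr[node + 1L, "ii"], d = 0),
      d = c(m = tr[node + 1L, "dm"], i = 0,
            d = if (node < hmm$M) tr[node + 1L, "dd"] else 0))
    nxt <- sample(c("m", "i", "d"), 1L, prob = moves)
    if (nxt == "i") {
      res <- c(res, sample(AA20, 1L, prob = hmm$insert_emissions[node + 1L, ]))
      state <- "i"
    } else {
      node <- node + 1L
      if (node > hmm$M) break
      if (nxt == "m") {
        res <- c(res, sample(AA20, 1L, prob = hmm$match_emissions[node, ]))
      }
      state <- nxt
    }
  }
  paste(res, collapse = "")
}
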