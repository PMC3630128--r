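# Quality metrics and leave-one-out cross-validation. Every labeled
# sequence falls in exactly one of three bins: correct (reliable and the
# predicted substrate matches the truth, synonyms allowed), false (reliable
# but mismatched), or below threshold (unreliable -- regardless of what the
# best model says). Coverage is the fraction of sequences receiving a
# reliable annotation; correct-of-covered is the correct fraction within
# those.

#' Evaluate a library on labeled sequences
#'
#' @param library A fitted `substrate_hmm`.
#' @param sequences Domain-sequence `data.frame` or named character vector
#'   of unaligned residues.
#' @param annotation Annotation `data.frame` labeling every sequence
#'   (`seq_id`, `substrate`); an unlabeled sequence is a hard error.
#' @param synonyms Synonym groups (see [substrate_synonyms()]); a
#'   prediction matching any code in the truth label's group is correct.
#'   Truth labels given as a `/`-separated list (ambiguous specificity) are
#'   correct if the prediction matches any listed substrate.
#' @param threshold_bits Optional threshold override.
#' @return Object of class `validation_report`: `per_substrate` counts
#'   (`substrate`, `n`, `correct`, `false`, `below_threshold`), `overall`
#'   percentages recomputed from the integer counts, and the per-sequence
#'   `records`.
#' @export
evaluate_library <- function(library, sequences, annotation,
                             synonyms = substrate_synonyms(library$domain_type),
                             threshold_bits = library$threshold_bits) {
  seqs <- query_seqs(sequences)
  truth <- annotation$substrate[match(names(seqs), annotation$seq_id)]
  if (anyNA(truth)) {
    stopf("unlabeled sequence(s): %s",
          paste(names(seqs)[is.na(truth)], collapse = ", "))
  }
  pred <- predict.substrate_hmm(library, sequences,
                                threshold_bits = threshold_bits)
  correct <- mapply(label_match, pred$substrate, truth,
                    MoreArgs = list(synonyms = synonyms))
  records <- data.frame(
    seq_id = pred$seq_id, truth = truth, predicted = pred$substrate,
    bits = pred$bits, reliable = pred$reliable,
    outcome = ifelse(!pred$reliable, "below_threshold",
                     ifelse(correct, "correct", "false")),
    stringsAsFactors = FALSE)
  validation_report(records)
}

# ambiguous truth labels ("a/b") count as correct on any listed substrate
label_match <- function(predicted, truth, synonyms) {
  parts <- strsplit(truth, "/", fixed = TRUE)[[1L]]
  any(codes_equivalent(rep(predicted, length(parts)), parts, synonyms))
}

validation_report <- function(records, flags = character(0)) {
  agg <- function(outc) {
    tapply(records$outcome == outc, records$truth, sum)
  }
  subs <- sort(unique(records$truth))
  per <- data.frame(
    substrate = subs,
    n = as.integer(table(factor(records$truth, levels = subs))),
    correct = as.integer(agg("correct")[subs]),
    false = as.integer(agg("false")[subs]),
    below_threshold = as.integer(agg("below_threshold")[subs]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_substrate = per,
                 overall = overall_metrics(per),
                 records = records, flags = flags),
            class = "validation_report")
}

# all overall percentages derive from the integer counts; nothing is stored
# pre-rounded
overall_metrics <- function(per) {
  n <- sum(per$n)
  correct <- sum(per$correct)
  false <- sum(per$false)
  below <- sum(per$below_threshold)
  covered <- correct + false
  list(n = n,
       percent_correct = 100 * correct / n,
       percent_false = 100 * false / n,
       percent_below_threshold = 100 * below / n,
       coverage_percent = 100 * (1 - below / n),
       correct_of_covered_percent =
         if (covered > 0) 100 * correct / covered else NA_real_)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n")
  print(x$per_substrate, row.names = FALSE)
  o <- x$overall
  cat(sprintf(
    "overall (n=%d): correct %.1f%%, false %.1f%%, below threshold %.1f%%\n",
    o$n, o$percent_correct, o$percent_false, o$percent_below_threshold))
  cat(sprintf("coverage %.1f%%, correct of covered %.1f%%\n",
              o$coverage_percent, o$correct_of_covered_percent))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.validation_report <- function(x, ...) {
  per <- x$per_substrate
  m <- t(as.matrix(per[, c("correct", "false", "below_threshold")]))
  graphics::barplot(m, names.arg = per$substrate, las = 2,
                    legend.text = c("correct", "false", "below threshold"),
                    main = "Classification outcome per substrate", ...)
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For every training sequence, only the model of its own (sub)group is
#' rebuilt without it -- sibling parts and other substrates' models stay
#' untouched -- and the held-out sequence (ungapped) is classified against
#' the full rebuilt library. Groups of size 2 degrade to single-member
#' models for the fold and are flagged; if removal empties a one-member
#' part, that model is dropped for the fold and the event flagged.
#' Sequences whose model has no other use (excluded singleton substrates)
#' are not evaluated.
#'
#' @param fit A `substrate_hmm` fitted by [substrate_hmm()] (the training
#'   alignment must be attached).
#' @param synonyms Synonym groups for correctness matching.
#' @return A `validation_report` whose `records` carry one row per
#'   held-out sequence.
#' @export
loo_cross_validate <- function(fit,
                               synonyms = substrate_synonyms(fit$domain_type)) {
  stopifnot(inherits(fit, "substrate_hmm"))
  if (is.null(fit$alignment)) {
    stopf("fit carries no training alignment; refit with substrate_hmm()")
  }
  flags <- character(0)
  rows <- list()
  for (model_name in names(fit$models)) {
    members <- fit$groups[[model_name]]
    if (length(members) < 2L) {
      flags <- c(flags, sprintf(
        "model '%s' has a single member; dropped per fold", model_name))
    }
    if (length(members) == 2L) {
      flags <- c(flags, sprintf(
        "group of model '%s' has size 2; folds use single-member models",
        model_name))
    }
    for (held in members) {
      rest <- setdiff(members, held)
      lib <- fit
      if (length(rest) == 0L) {
        lib$models[[model_name]] <- NULL
        lib$groups[[model_name]] <- NULL
      } else {
        sub_aln <- subset_alignment(fit$alignment, rows = rest)
        m0 <- fit$models[[model_name]]
        lib$models[[model_name]] <- build_profile_hmm(
          sub_aln, name = m0$name, substrate = m0$substrate,
          subgroup = m0$subgroup, pseudocount = fit$pseudocount,
          background = fit$background)
        lib$groups[[model_name]] <- rest
      }
      if (!length(lib$models)) next
      query <- stats::setNames(ungap(fit$alignment$seqs[[held]]), held)
      truth <- fit$models[[model_name]]$substrate
      pred <- predict.substrate_hmm(lib, query)
      rows[[held]] <- data.frame(
        seq_id = held, truth = truth, predicted = pred$substrate,
        bits = pred$bits, reliable = pred$reliable,
        outcome = if (!pred$reliable) "below_threshold"
                  else if (label_match(pred$substrate, truth, synonyms))
                    "correct" else "false",
        model = model_name, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stopf("no sequences could be cross-validated")
  validation_report(do.call(rbind, rows), flags = unique(flags))
}

#' Compare two validation reports
#'
#' Aligns the per-substrate rows of two reports and returns count and
#' percentage differences (`b - a`).
#'
#' @param a,b `validation_report` objects over the same substrate
#'   vocabulary.
#' @return `data.frame` of per-substrate deltas plus an `overall`
#'   attribute with the overall percentage deltas.
#' @export
compare_reports <- function(a, b) {
  stopifnot(inherits(a, "validation_report"), inherits(b, "validation_report"))
  subs <- sort(union(a$per_substrate$substrate, b$per_substrate$substrate))
  pick <- function(rep, col) {
    v <- rep$per_substrate[[col]][match(subs, rep$per_substrate$substrate)]
    ifelse(is.na(v), 0L, v)
  }
  out <- data.frame(
    substrate = subs,
    d_n = pick(b, "n") - pick(a, "n"),
    d_correct = pick(b, "correct") - pick(a, "correct"),
    d_false = pick(b, "false") - pick(a, "false"),
    d_below_threshold = pick(b, "below_threshold") - pick(a, "below_threshold"),
    stringsAsFactors = FALSE)
  attr(out, "overall") <- list(
    d_percent_correct = b$overall$percent_correct - a$overall$percent_correct,
    d_coverage_percent = b$overall$coverage_percent - a$overall$coverage_percent)
  out
}
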