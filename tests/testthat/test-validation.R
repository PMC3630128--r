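two_group_fit <- function(seed = 33, threshold = NULL) {
  ds <- simulate_family(simulation_config(
    seed = seed, scaffold_length = 100L,
    group_sizes = c(G1 = 6L, G2 = 6L), specificity_positions = 6L,
    scaffold_mutation_rate = 0.02, stem_rounds = 6L))
  thr <- if (is.null(threshold)) calibrate_threshold(ds)$threshold_bits
         else threshold
  list(ds = ds,
       fit = substrate_hmm(ds$alignment, ds$annotation, "single", "A",
                           threshold_bits = thr))
}

test_that("evaluation bins every sequence and derives percentages from counts", {
  x <- two_group_fit()
  rep <- evaluate_library(x$fit, x$ds$sequences, x$ds$annotation)
  per <- rep$per_substrate
  expect_equal(per$correct + per$false + per$below_threshold, per$n)
  o <- rep$overall
  expect_equal(o$percent_correct,
               100 * sum(per$correct) / sum(per$n), tolerance = 1e-12)
  expect_equal(o$coverage_percent,
               100 * (1 - sum(per$below_threshold) / sum(per$n)),
               tolerance = 1e-12)
  expect_equal(o$correct_of_covered_percent,
               100 * sum(per$correct) / (sum(per$correct) + sum(per$false)),
               tolerance = 1e-12)

  # resubstitution on a well-separated fixture is fully correct
  expect_equal(o$percent_correct, 100)

  # unlabeled sequences are a hard error
  expect_error(
    evaluate_library(x$fit, c(mystery = x$ds$sequences$residues[1]),
                     x$ds$annotation),
    "unlabeled")
})

test_that("the three-way bookkeeping matches a worked 4-sequence example", {
  # force outcomes by hand: 2 correct, 1 false, 1 below threshold
  x <- two_group_fit()
  seqs <- x$ds$sequences[c(1, 2, 3, 7), ]
  annot <- x$ds$annotation
  annot$substrate[annot$seq_id == seqs$id[3]] <- "G2"  # mislabel -> false
  pred <- predict(x$fit, seqs)
  # push one sequence below threshold via a raised per-call threshold
  thr <- sort(pred$bits)[1] + 0.5
  rep <- evaluate_library(x$fit, seqs, annot, threshold_bits = thr)
  o <- rep$overall
  expect_equal(o$n, 4L)
  expect_equal(o$coverage_percent, 75.0)
  expect_equal(round(o$correct_of_covered_percent, 1), 66.7)
})

test_that("synonymous and ambiguous labels count as correct", {
  x <- two_group_fit()
  seqs <- x$ds$sequences[1:2, ]
  annot <- x$ds$annotation
  # ambiguous truth: either substrate acceptable
  annot$substrate <- paste0(annot$substrate, "/G2")
  rep <- evaluate_library(x$fit, seqs, annot, synonyms = list())
  expect_equal(rep$overall$percent_correct, 100)

  # synonym group: predictions of G1 for truth G2 become correct
  annot2 <- x$ds$annotation
  annot2$substrate <- "G2"
  rep2 <- evaluate_library(x$fit, seqs, annot2,
                           synonyms = list(c("G1", "G2")))
  expect_equal(rep2$overall$percent_correct, 100)
})

test_that("report numbers are invariant to input order", {
  x <- two_group_fit()
  seqs <- x$ds$sequences
  rep1 <- evaluate_library(x$fit, seqs, x$ds$annotation)
  rep2 <- evaluate_library(x$fit, seqs[rev(seq_len(nrow(seqs))), ],
                           x$ds$annotation)
  expect_identical(rep1$per_substrate, rep2$per_substrate)
  expect_identical(rep1$overall, rep2$overall)
})

test_that("LOO on identical training sequences stays correct", {
  aln <- new_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL",
                         c = "ACDEFGHIKL",
                         x = "LMNPQRSTVW", y = "LMNPQRSTVW"))
  annot <- data.frame(seq_id = c("a", "b", "c", "x", "y"),
                      substrate = c("P", "P", "P", "Q", "Q"))
  fit <- substrate_hmm(aln, annot, "single", "A", threshold_bits = 10)
  loo <- loo_cross_validate(fit)
  expect_equal(loo$overall$percent_correct, 100)
  expect_equal(nrow(loo$records), 5L)
  # size-2 group is flagged as degraded
  expect_true(any(grepl("size 2", loo$flags)))
})

test_that("re-inserting a held-out sequence reproduces resubstitution bit-for-bit", {
  x <- two_group_fit()
  fit <- x$fit
  held <- fit$groups[["G1"]][1L]
  rest <- setdiff(fit$groups[["G1"]], held)
  # fold model without the held-out sequence, then rebuilt with it again
  refit <- build_profile_hmm(
    substrateHMM:::subset_alignment(fit$alignment, rows = fit$groups[["G1"]]),
    name = "G1", substrate = "G1", pseudocount = fit$pseudocount,
    background = fit$background)
  expect_identical(refit$match_emissions, fit$models$G1$match_emissions)
  q <- substrateHMM:::ungap(fit$alignment$seqs[[held]])
  expect_identical(viterbi_bits(refit, q)$bit_score,
                   viterbi_bits(fit$models$G1, q)$bit_score)
})

test_that("LOO never beats resubstitution on the same fixture", {
  x <- two_group_fit()
  resub <- evaluate_library(x$fit, x$ds$sequences, x$ds$annotation)
  loo <- loo_cross_validate(x$fit)
  expect_lte(loo$overall$percent_correct, resub$overall$percent_correct)
})

test_that("ensemble LOO rebuilds only the held-out sequence's own part", {
  ds <- convergent_benchmark(seed = 3)
  fit <- substrate_hmm(ds$alignment, ds$annotation, "ensemble", "A",
                       threshold_bits = ds$threshold_bits,
                       size_threshold = 15, partitions = ds$partitions)
  loo <- loo_cross_validate(fit)
  expect_equal(nrow(loo$records), nrow(ds$sequences))
  expect_setequal(unique(loo$records$model[loo$records$truth == "S1"]),
                  c("S1_1", "S1_2"))
})

test_that("report comparison is antisymmetric and zero against itself", {
  x <- two_group_fit()
  rep <- evaluate_library(x$fit, x$ds$sequences, x$ds$annotation)
  d0 <- compare_reports(rep, rep)
  expect_true(all(d0$d_correct == 0 & d0$d_false == 0 &
                    d0$d_below_threshold == 0))
  loo <- loo_cross_validate(x$fit)
  dab <- compare_reports(rep, loo)
  dba <- compare_reports(loo, rep)
  expect_equal(dab$d_correct, -dba$d_correct)
  expect_equal(attr(dab, "overall")$d_percent_correct,
               -attr(dba, "overall")$d_percent_correct)
})
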