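test_that("match columns are those with gap fraction at most one half", {
  expect_equal(assign_match_columns(make_alignment(a = "ACD", b = "ACD")),
               rep(TRUE, 3))
  # 2 gaps of 3 rows -> insert column
  aln <- make_alignment(a = "A-", b = "AC", c = "A-")
  expect_equal(assign_match_columns(aln), c(TRUE, FALSE))
  # 2 gaps of 4 rows -> tie -> match column
  aln2 <- make_alignment(a = "A-", b = "AC", c = "A-", d = "AC")
  expect_equal(assign_match_columns(aln2), c(TRUE, TRUE))
})

test_that("maximum-likelihood training reproduces counts and state paths", {
  # single row, no smoothing: deterministic emissions
  h <- build_profile_hmm(make_alignment(r = "AC"), "m", "S", pseudocount = 0)
  expect_equal(h$M, 2L)
  expect_equal(unname(h$match_emissions[1, "A"]), 1)
  expect_equal(unname(h$match_emissions[2, "C"]), 1)
  expect_equal(unname(rowSums(h$match_emissions)), rep(1, 2))

  # row 2 of {"AC","A-"} traverses M1 -> D2; the transition shows up
  h2 <- build_profile_hmm(make_alignment(a = "AC", b = "A-"), "m2", "S",
                          pseudocount = 0)
  expect_equal(unname(h2$transitions[2, "md"]), 0.5)  # 1 of 2 rows leaves M1 for D2
  expect_equal(unname(h2$transitions[2, "mm"]), 0.5)
  expect_equal(unname(h2$transitions[3, "dm"]), 1)    # D2 always exits to end
})

test_that("trained models always satisfy the stochasticity invariants", {
  set.seed(67)
  for (r in 1:12) {
    n <- sample(2:6, 1L)
    len <- sample(5:15, 1L)
    rows <- vapply(seq_len(n), function(i) {
      s <- strsplit(random_residues(len), "")[[1L]]
      s[stats::runif(len) < 0.2] <- "-"
      paste(s, collapse = "")
    }, "")
    names(rows) <- paste0("r", seq_len(n))
    aln <- new_alignment(rows)
    flags <- try(assign_match_columns(aln), silent = TRUE)
    if (inherits(flags, "try-error")) next
    h <- build_profile_hmm(aln, "m", "S", pseudocount = stats::runif(1, 0.1, 2))
    expect_equal(unname(rowSums(h$match_emissions)), rep(1, h$M),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(h$insert_emissions)), rep(1, h$M + 1),
                 tolerance = 1e-9)
    tr <- h$transitions
    for (nd in 0:h$M) {
      m_moves <- if (nd < h$M) c("mm", "mi", "md") else c("mm", "mi")
      expect_equal(sum(tr[nd + 1, m_moves]), 1, tolerance = 1e-9)
      expect_equal(sum(tr[nd + 1, c("im", "ii")]), 1, tolerance = 1e-9)
      if (nd > 0) {
        d_moves <- if (nd < h$M) c("dm", "dd") else "dm"
        expect_equal(sum(tr[nd + 1, d_moves]), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("duplicating every training row leaves the unsmoothed model unchanged", {
  aln <- make_alignment(a = "ACD", b = "AC-", c = "GCD")
  doubled <- new_alignment(c(aln$seqs,
                             stats::setNames(aln$seqs, paste0(names(aln$seqs), "_2"))))
  h1 <- build_profile_hmm(aln, "m", "S", pseudocount = 0)
  h2 <- build_profile_hmm(doubled, "m", "S", pseudocount = 0)
  expect_equal(h1$match_emissions, h2$match_emissions, tolerance = 1e-12)
  expect_equal(h1$transitions, h2$transitions, tolerance = 1e-12)
})

test_that("a perfect one-state match scores log2(20) bits", {
  h <- build_profile_hmm(make_alignment(r = "A"), "m", "S", pseudocount = 0)
  s <- viterbi_bits(h, "A")
  expect_equal(s$bit_score, log2(20), tolerance = 1e-9)
  expect_equal(s$raw_log_odds, log(20), tolerance = 1e-9)
  expect_equal(s$path_length, 1L)
})

test_that("Viterbi equals the exhaustive path-enumeration oracle", {
  set.seed(101)
  for (r in 1:60) {
    h <- random_hmm()
    s <- random_residues(sample(1:6, 1L), with_x = (r %% 6 == 0))
    expect_equal(viterbi_bits(h, s)$bit_score, brute_force_viterbi(h, s),
                 tolerance = 1e-9)
  }
})

test_that("scores are finite under smoothing and invariant to renaming", {
  set.seed(103)
  aln <- new_alignment(stats::setNames(
    vapply(1:3, function(i) random_residues(12L), ""), c("a", "b", "c")))
  h <- build_profile_hmm(aln, "m", "S", pseudocount = 1)
  for (r in 1:10) {
    q <- random_residues(sample(c(3L, 12L, 25L), 1L), with_x = TRUE)
    expect_true(is.finite(viterbi_bits(h, q)$bit_score))
  }
  h2 <- h
  h2$name <- "renamed"
  q <- random_residues(12L)
  expect_equal(viterbi_bits(h, q)$bit_score, viterbi_bits(h2, q)$bit_score)
})

test_that("score_all ranks models by bits with name tie-breaks", {
  aln <- make_alignment(a = "ACDE", b = "ACDE", c = "GGDE", d = "GGDE")
  annot <- data.frame(seq_id = letters[1:4],
                      substrate = c("S1", "S1", "S2", "S2"))
  lib <- substrate_hmm(new_alignment(aln$seqs), annot, "single", "A",
                       threshold_bits = 0)
  sc <- score_all(lib, "ACDE")
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$model[1L], "S1")
  expect_true(all(diff(sc$bits) <= 0))

  # exact tie: two identical models under different names -> name order
  lib2 <- lib
  lib2$models <- list(zzz = lib$models$S1, aaa = lib$models$S1)
  lib2$models$zzz$name <- "zzz"
  lib2$models$aaa$name <- "aaa"
  sc2 <- score_all(lib2, "ACDE")
  expect_equal(sc2$model, c("aaa", "zzz"))
})

test_that("in-group sequences outscore out-group sequences on their model", {
  ds <- simulate_family(simulation_config(
    seed = 13, scaffold_length = 100L,
    group_sizes = c(G1 = 8L, G2 = 8L), specificity_positions = 6L,
    scaffold_mutation_rate = 0.03, stem_rounds = 6L))
  groups <- split(ds$annotation$seq_id, ds$annotation$substrate)
  lib <- build_single_library(groups, "A", threshold_bits = 0,
                              alignment = ds$alignment)
  for (g in names(groups)) {
    m <- lib$models[[g]]
    in_bits <- vapply(groups[[g]], function(id)
      viterbi_bits(m, ds$sequences$residues[ds$sequences$id == id])$bit_score, 0)
    out_ids <- setdiff(ds$sequences$id, groups[[g]])
    out_bits <- vapply(out_ids, function(id)
      viterbi_bits(m, ds$sequences$residues[ds$sequences$id == id])$bit_score, 0)
    expect_gt(mean(in_bits), mean(out_bits))
  }
})
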