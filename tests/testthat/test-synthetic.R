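test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 99, scaffold_length = 60L,
                           group_sizes = c(A1 = 4L, B1 = 3L),
                           specificity_positions = 4L,
                           scaffold_mutation_rate = 0.05)
  d1 <- simulate_family(cfg)
  d2 <- simulate_family(cfg)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(ape::write.tree(d1$true_tree), ape::write.tree(d2$true_tree))

  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(d1$sequences, f1)
  write_fasta(d2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))

  # and the caller's RNG stream is left untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_family(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("zero mutation rate collapses each label to identical sequences", {
  ds <- simulate_family(simulation_config(
    seed = 2, scaffold_length = 50L, group_sizes = c(A1 = 5L, B1 = 4L),
    specificity_positions = 3L, scaffold_mutation_rate = 0))
  for (l in c("A1", "B1")) {
    members <- ds$sequences$residues[ds$sequences$substrate == l]
    expect_length(unique(members), 1L)
  }
})

test_that("planted signatures are present at the planted positions", {
  ds <- simulate_family(simulation_config(
    seed = 7, scaffold_length = 80L,
    group_sizes = c(A1 = 6L, B1 = 6L), specificity_positions = 5L,
    scaffold_mutation_rate = 0.08, stem_rounds = 4L))
  # disjoint positions
  expect_length(unlist(ds$planted_positions),
                length(unique(unlist(ds$planted_positions))))
  for (i in seq_len(nrow(ds$sequences))) {
    lab <- ds$sequences$substrate[i]
    sig <- ds$signatures[[lab]]
    res <- strsplit(ds$sequences$residues[i], "")[[1L]]
    expect_identical(res[as.integer(names(sig))], unname(sig))
  }
})

test_that("generator output passes the package validators", {
  ds <- simulate_family(simulation_config(seed = 10, scaffold_length = 40L,
                                          group_sizes = c(A1 = 3L, B1 = 3L),
                                          specificity_positions = 3L,
                                          scaffold_mutation_rate = 0.05))
  f <- tempfile(fileext = ".fasta")
  write_fasta(ds$sequences, f)
  expect_silent(back <- read_fasta(f, "A"))
  expect_identical(back$residues, ds$sequences$residues)
  ft <- tempfile(fileext = ".tsv")
  write_annotation(ds$annotation, ft)
  expect_silent(read_annotation(ft, ds$vocabulary))
  fn <- tempfile(fileext = ".nwk")
  write_newick(ds$true_tree, fn)
  expect_setequal(read_newick(fn)$tip.label, ds$sequences$id)
})

test_that("terminal extensions are recorded and reversible by trimming", {
  ds <- simulate_family(simulation_config(
    seed = 14, scaffold_length = 60L, group_sizes = c(A1 = 5L, B1 = 5L),
    specificity_positions = 4L, scaffold_mutation_rate = 0.04))
  # zero-length distribution: unchanged
  same <- add_terminal_extensions(ds, lengths = 0L, seed = 1)
  expect_identical(same$sequences, ds$sequences)

  padded <- add_terminal_extensions(ds, lengths = 2:6, seed = 5)
  added <- sum(padded$truth$pad_left + padded$truth$pad_right)
  expect_equal(sum(nchar(padded$sequences$residues)) -
                 sum(nchar(ds$sequences$residues)), added)
  expect_gt(added, 0)

  # trimming with the truth-scripted realigner recovers the core exactly
  out <- trim_terminal_extensions(padded$sequences, padding_realigner(padded))
  expect_equal(unname(terminal_overhang(out)), c(0L, 0L))
  got <- vapply(out$seqs, function(s) gsub("-", "", s), "", USE.NAMES = TRUE)
  expect_identical(got[ds$sequences$id],
                   stats::setNames(ds$sequences$residues, ds$sequences$id))
})

test_that("the convergent benchmark plants one label in exactly two clades", {
  ds <- convergent_benchmark(seed = 5)
  s1_clades <- unique(ds$truth$clade[ds$truth$label == "S1"])
  expect_length(s1_clades, 2L)
  expect_length(unique(ds$truth$clade[ds$truth$label == "S2"]), 1L)
  # the partition shipped with the benchmark is the true clade split
  expect_setequal(ds$partitions$S1[[1L]],
                  ds$truth$seq_id[ds$truth$clade == "S1_c1"])
  expect_setequal(ds$partitions$S1[[2L]],
                  ds$truth$seq_id[ds$truth$clade == "S1_c2"])
  # calibrated threshold lies between the score distributions it separates
  expect_lt(ds$manifest$mean_out_group_bits, ds$threshold_bits)
  expect_gt(ds$manifest$mean_in_group_bits, ds$threshold_bits)
})

test_that("NJ on simulated alignments separates the planted clades", {
  ds <- convergent_benchmark(seed = 5)
  tree <- nj_tree(ds$alignment)
  # the two convergent sub-clades are monophyletic and distinct
  for (cl in c("S1_c1", "S1_c2")) {
    ids <- ds$truth$seq_id[ds$truth$clade == cl]
    expect_true(ape::is.monophyletic(tree, ids))
  }
  # within-clade distances are smaller than the cross-clade distances
  d <- pairwise_distances(ds$alignment)
  c1 <- ds$truth$seq_id[ds$truth$clade == "S1_c1"]
  c2 <- ds$truth$seq_id[ds$truth$clade == "S1_c2"]
  expect_lt(max(d[c1, c1]), min(d[c1, c2]))
})

test_that("low-noise simulations let NJ recover the generating topology", {
  cfg <- simulation_config(seed = 31, scaffold_length = 400L,
                           group_sizes = c(A1 = 4L, B1 = 4L),
                           specificity_positions = 4L,
                           scaffold_mutation_rate = 0.01,
                           stem_rounds = 12L)
  ds <- simulate_family(cfg)
  nj <- nj_tree(ds$alignment)
  expect_equal(phangorn::RF.dist(ape::unroot(nj),
                                 ape::unroot(ds$true_tree)), 0)
})
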