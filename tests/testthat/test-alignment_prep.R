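test_that("terminal overhang counts leading/trailing gap-containing columns", {
  expect_equal(unname(terminal_overhang(make_alignment(a = "MKL", b = "MKL"))),
               c(0L, 0L))
  expect_equal(unname(terminal_overhang(make_alignment(a = "-KL", b = "MKL"))),
               c(1L, 0L))
  expect_equal(unname(terminal_overhang(make_alignment(a = "--KLA",
                                                       b = "MAKL-"))),
               c(2L, 1L))
})

test_that("trimming removes terminal extensions and reaches a fixed point", {
  # already homogeneous: returned unchanged
  aln0 <- make_alignment(a = "MKLV", b = "MKLV")
  out <- trim_terminal_extensions(c(a = "MKLV", b = "MKLV"),
                                  identity_realigner())
  expect_identical(out$seqs, aln0$seqs)
  expect_equal(unname(attr(out, "removed")), c(0L, 0L))
  expect_true(attr(out, "converged"))

  # one sequence with 5 extra N-terminal residues; the scripted realigner
  # plays the initial overhanging alignment, then the clean core
  core <- c(a = "MKLVDE", b = "MKLVDE")
  padded <- c(a = paste0("WWWWW", core[["a"]]), b = core[["b"]])
  a1 <- make_alignment(a = padded[["a"]], b = paste0("-----", core[["b"]]))
  out <- trim_terminal_extensions(padded,
                                  scripted_realigner(list(a1,
                                                          make_alignment(a = core[["a"]], b = core[["b"]]))))
  expect_equal(unname(terminal_overhang(out)), c(0L, 0L))
  expect_equal(attr(out, "removed")[["a"]], 5L)
  expect_equal(attr(out, "removed")[["b"]], 0L)

  # trimming its own output changes nothing (idempotence)
  again <- trim_terminal_extensions(vapply(out$seqs, function(s)
    gsub("-", "", s), "", USE.NAMES = TRUE), identity_realigner())
  expect_identical(again$seqs, out$seqs)
})

test_that("trimming only ever removes a prefix/suffix of each sequence", {
  set.seed(31)
  ds <- simulate_family(simulation_config(
    seed = 5, scaffold_length = 60L,
    group_sizes = c(A1 = 4L, B1 = 4L), specificity_positions = 4L,
    scaffold_mutation_rate = 0.05))
  padded <- add_terminal_extensions(ds, lengths = 2:6, seed = 11)
  out <- trim_terminal_extensions(padded$sequences,
                                  padding_realigner(padded))
  for (id in names(out$seqs)) {
    trimmed <- gsub("-", "", out$seqs[[id]])
    original <- padded$sequences$residues[padded$sequences$id == id]
    expect_true(grepl(trimmed, original, fixed = TRUE))
  }
})

test_that("trimming errors when a sequence would vanish and warns on stall", {
  # sequence b is pure extension relative to a: trimming empties it
  a1 <- make_alignment(a = "MK--", b = "--VV")
  expect_error(
    trim_terminal_extensions(c(a = "MK", b = "VV"),
                             scripted_realigner(list(a1))),
    "trimming would remove every column|trimmed to length 0")

  # a realigner that always reintroduces an overhang never converges
  stubborn <- function(seqs) {
    w <- max(nchar(seqs)) + 1L
    new_alignment(vapply(seqs, function(s)
      paste0(strrep("-", w - nchar(s)), s), "", USE.NAMES = TRUE))
  }
  expect_warning(
    out <- trim_terminal_extensions(c(a = "MKLVVA", b = "MKLVV"),
                                    stubborn, max_rounds = 3L),
    "did not converge")
  expect_false(attr(out, "converged"))
})

test_that("deduplication is greedy, same-substrate only, and idempotent", {
  # byte-identical duplicates: second removed at any threshold
  seqs <- domain_sequences(c("x", "y"), c("MKLV", "MKLV"), "AT",
                           substrate = c("MC", "MC"))
  dd <- deduplicate(seqs, 0.98)
  expect_equal(dd$kept$id, "x")
  expect_equal(dd$removed$removed_id, "y")
  expect_equal(dd$removed$identity, 1.0)

  # identical residues but different substrates: both kept
  seqs2 <- domain_sequences(c("x", "y"), c("MKLV", "MKLV"), "AT",
                            substrate = c("MC", "MMC"))
  expect_equal(nrow(deduplicate(seqs2, 0.98)$kept), 2L)

  expect_error(deduplicate(seqs, 0.4), "identity_threshold")
})

test_that("near-duplicate removal matches brute-force identity screening", {
  set.seed(17)
  base <- vapply(1:7, function(i) random_residues(50L), "")
  # sequences 8-10 are 98-100% copies of base[1] (0-1 substitutions)
  copies <- vapply(1:3, function(i) {
    s <- strsplit(base[1], "")[[1]]
    k <- sample(0:1, 1L)
    if (k > 0) {
      p <- sample(50L, k)
      s[p] <- vapply(s[p], function(ch) sample(setdiff(aa_alphabet(), ch), 1L), "")
    }
    paste(s, collapse = "")
  }, "")
  all10 <- c(base, copies)
  seqs <- domain_sequences(sprintf("q%02d", 1:10), all10, "A",
                           substrate = "ala")
  dd <- deduplicate(seqs, identity_threshold = 0.98)

  # brute-force oracle: greedy scan using raw Hamming identity (equal
  # lengths, no indels simulated, so alignment identity == Hamming)
  ham <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    mean(ca == cb)
  }
  kept <- character(0)
  for (s in all10) {
    if (!any(vapply(kept, function(k) ham(k, s) >= 0.98, logical(1)))) {
      kept <- c(kept, s)
    }
  }
  expect_equal(nrow(dd$kept), length(kept))
  expect_equal(nrow(dd$kept) + nrow(dd$removed), 10L)

  # idempotence: deduplicating the kept set removes nothing
  dd2 <- deduplicate(dd$kept, identity_threshold = 0.98)
  expect_equal(dd2$kept$id, dd$kept$id)
  expect_equal(nrow(dd2$removed), 0L)
})

test_that("pairwise identity handles indels through global alignment", {
  # one residue deleted: 9 matches over 10 aligned columns
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEGHIKL"), 0.9)
  expect_equal(pairwise_identity("ACDEF", "ACDEF"), 1.0)
})

test_that("mafft realigner satisfies the realigner contract", {
  set.seed(3)
  core <- random_residues(40L)
  seqs <- c(a = core, b = paste0("MKV", core), c = core)
  aln <- mafft_realigner()(seqs)
  expect_s3_class(aln, "domain_msa")
  expect_setequal(names(aln$seqs), names(seqs))
  expect_identical(gsub("-", "", aln$seqs[["b"]]), seqs[["b"]])
})
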