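# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# ---- brute-force Viterbi by exhaustive path enumeration --------------------
# Enumerates every legal state path through the match/insert/delete profile
# that consumes the whole sequence, summing log2 emission odds and log2
# transition probabilities, and returns the maximum.
brute_force_viterbi <- function(hmm, seq) {
  x <- strsplit(toupper(seq), "")[[1L]]
  L <- length(x)
  M <- hmm$M
  lo_m <- cbind(log2(sweep(hmm$match_emissions, 2, hmm$background, `/`)), X = 0)
  lo_i <- cbind(log2(sweep(hmm$insert_emissions, 2, hmm$background, `/`)), X = 0)
  tr <- suppressWarnings(log2(hmm$transitions))
  xi <- match(x, colnames(lo_m))
  best <- -Inf
  rec <- function(state, node, i, sc) {
    if (sc == -Inf) return(invisible())
    # move towards match/end
    mv <- paste0(state, "m")
    if (node == M) {
      if (i == L) best <<- max(best, sc + tr[node + 1L, mv])
    } else if (i < L) {
      rec("m", node + 1L, i + 1L,
          sc + tr[node + 1L, mv] + lo_m[node + 1L, xi[i + 1L]])
    }
    # insert (not from delete)
    if (state != "d" && i < L) {
      rec("i", node, i + 1L,
          sc + tr[node + 1L, paste0(state, "i")] + lo_i[node + 1L, xi[i + 1L]])
    }
    # delete (not from insert), no D_{M+1}
    if (state != "i" && node < M) {
      rec("d", node + 1L, i, sc + tr[node + 1L, paste0(state, "d")])
    }
  }
  rec("m", 0L, 0L, 0)
  best
}

# ---- random small profile HMMs --------------------------------------------
rand_simplex <- function(n) {
  v <- stats::runif(n) + 1e-3
  v / sum(v)
}

random_hmm <- function(M = sample(1:4, 1L), name = "rnd") {
  aa <- aa_alphabet()
  me <- t(vapply(seq_len(M), function(k) rand_simplex(20L), numeric(20L)))
  colnames(me) <- aa
  ie <- t(vapply(seq_len(M + 1L), function(k) rand_simplex(20L), numeric(20L)))
  colnames(ie) <- aa
  tr <- matrix(0, M + 1L, 7L,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  for (nd in 0:M) {
    m_moves <- if (nd < M) c("mm", "mi", "md") else c("mm", "mi")
    tr[nd + 1L, m_moves] <- rand_simplex(length(m_moves))
    tr[nd + 1L, c("im", "ii")] <- rand_simplex(2L)
    if (nd > 0L) {
      d_moves <- if (nd < M) c("dm", "dd") else "dm"
      tr[nd + 1L, d_moves] <- rand_simplex(length(d_moves))
    }
  }
  structure(
    list(name = name, substrate = "S", subgroup = 0L, M = M, alphabet = aa,
         background = stats::setNames(rep(1 / 20, 20L), aa),
         match_emissions = me, insert_emissions = ie, transitions = tr,
         n_train = 0L),
    class = "profile_hmm")
}

random_residues <- function(len, with_x = FALSE) {
  pool <- c(aa_alphabet(), if (with_x) "X")
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# ---- additive distance matrices and exhaustive minimum evolution -----------
# random unrooted topology with branch lengths; returns the tree and its
# additive (path-length) matrix
random_additive_matrix <- function(n, min_bl = 0.05, max_bl = 0.3) {
  tr <- ape::rtree(n, rooted = FALSE, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = tr, d = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
}

# exhaustive minimum-evolution: OLS branch lengths on every unrooted
# topology, pick the one with the smallest total length
minimum_evolution_tree <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 6L)
  tips <- rownames(d)
  cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = tips)
  dd <- as.dist(d)
  best <- NULL
  best_len <- Inf
  for (ci in seq_along(cands)) {
    tr <- cands[[ci]]  # [[ ]] restores tip labels from the compressed store
    X <- phangorn::designTree(tr)
    bl <- qr.solve(as.matrix(X)[, colnames(X), drop = FALSE], as.vector(dd))
    len <- sum(bl)
    if (len < best_len - 1e-12) {
      best_len <- len
      best <- tr
    }
  }
  best
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

# ---- misc ------------------------------------------------------------------
make_alignment <- function(...) new_alignment(c(...))

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# a scripted realigner for a padded synthetic dataset: first call returns a
# block alignment (pads right/left-justified into their own columns), the
# second call the true gap-free core alignment
padding_realigner <- function(dataset) {
  core <- dataset$alignment$seqs
  tt <- dataset$truth
  lw <- max(tt$pad_left)
  rw <- max(tt$pad_right)
  rows <- character(0)
  for (i in seq_len(nrow(tt))) {
    id <- tt$seq_id[i]
    res <- dataset$sequences$residues[dataset$sequences$id == id]
    pl <- tt$pad_left[i]
    pr <- tt$pad_right[i]
    left <- paste0(strrep("-", lw - pl), substr(res, 1L, pl))
    right <- paste0(substr(res, nchar(res) - pr + 1L, nchar(res)),
                    strrep("-", rw - pr))
    if (pr == 0L) right <- strrep("-", rw)
    rows[id] <- paste0(left, core[[id]], right)
  }
  scripted_realigner(list(new_alignment(rows),
                          new_alignment(core)))
}
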