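# Distance matrices, Neighbor-Joining (Saitou-Nei), and the clade-guided
# partition of a substrate group into 2-4 subgroups for ensemble models.
# NJ is implemented here (rather than wrapped) so tie-breaking and
# negative-branch handling are fully specified and deterministic; ape::nj
# serves as an independent cross-check in the test suite.

#' Pairwise p-distances from an alignment
#'
#' `d(i, j)` = mismatches / comparable columns, where a column is comparable
#' when both rows carry a non-gap residue there. Pairs with no comparable
#' columns get distance 1 with a warning.
#'
#' @param alignment A `domain_msa`.
#' @return Symmetric numeric matrix with sequence ids as dimnames.
#' @export
pairwise_distances <- function(alignment) {
  stopifnot(inherits(alignment, "domain_msa"))
  m <- as.matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stopf("need at least 2 rows")
  gap <- matrix(is_gap(m), nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- !gap[i, ] & !gap[j, ]
      if (!any(comp)) {
        warnf("no comparable columns between '%s' and '%s'; distance set to 1",
              rownames(m)[i], rownames(m)[j])
        d[i, j] <- d[j, i] <- 1
      } else {
        d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
      }
    }
  }
  d
}

#' Neighbor-Joining tree
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` (`r` = row sums), with branch lengths
#' `L(i,u) = d(i,j)/2 + (r_i - r_j) / (2(n-2))`, reduce the matrix by
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`, and close with the three-taxon
#' star formulas. Ties in Q are broken by the lexicographically smallest
#' pair of cluster representatives (the smallest leaf id in each cluster),
#' making the result independent of input order. Negative branch lengths
#' are clamped to 0 with the deficit moved to the sister branch, preserving
#' the path length between the joined clusters.
#'
#' @param d Symmetric distance matrix with unique dimnames, >= 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("d must be a square matrix")
  ids <- rownames(d)
  if (is.null(ids) || anyDuplicated(ids)) {
    stopf("d needs unique rownames")
  }
  n0 <- nrow(d)
  if (n0 < 3L) stopf("neighbor joining needs at least 3 taxa")
  # order rows lexicographically so index-based scanning is order-invariant
  ord <- order(ids)
  d <- d[ord, ord, drop = FALSE]
  ids <- ids[ord]
  frag <- stats::setNames(ids, ids)    # newick fragment per active cluster
  rep_id <- stats::setNames(ids, ids)  # smallest leaf id per cluster
  active <- ids
  while (length(active) > 3L) {
    n <- length(active)
    dm <- d[active, active, drop = FALSE]
    r <- rowSums(dm)
    q <- (n - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # lexicographic tie-break on (rep_i, rep_j), reps sorted within the pair
    keys <- apply(cand, 1L, function(rc) {
      pr <- sort(c(rep_id[[active[rc[1L]]]], rep_id[[active[rc[2L]]]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    a <- active[pick[1L]]; b <- active[pick[2L]]
    dij <- dm[a, b]
    la <- dij / 2 + (r[a] - r[b]) / (2 * (n - 2))
    lb <- dij - la
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    u <- paste0("u", length(active))
    others <- setdiff(active, c(a, b))
    du <- (d[a, others] + d[b, others] - dij) / 2
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- u
    d[u, others] <- d[others, u] <- du
    frag[[u]] <- sprintf("(%s:%s,%s:%s)", frag[[a]], fmt_bl(la),
                         frag[[b]], fmt_bl(lb))
    rep_id[[u]] <- min(rep_id[[a]], rep_id[[b]])
    active <- c(others, u)
  }
  a <- active[1L]; b <- active[2L]; c_ <- active[3L]
  la <- max(0, (d[a, b] + d[a, c_] - d[b, c_]) / 2)
  lb <- max(0, (d[a, b] + d[b, c_] - d[a, c_]) / 2)
  lc <- max(0, (d[a, c_] + d[b, c_] - d[a, b]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[[a]], fmt_bl(la),
                 frag[[b]], fmt_bl(lb), frag[[c_]], fmt_bl(lc))
  ape::read.tree(text = nwk)
}

fmt_bl <- function(x) sprintf("%.10g", x)

#' Build an NJ tree from an alignment
#'
#' Convenience composition of [pairwise_distances()] and
#' [neighbor_joining()].
#'
#' @param alignment A `domain_msa` with >= 3 rows.
#' @return An `ape::phylo`.
#' @export
nj_tree <- function(alignment) {
  neighbor_joining(pairwise_distances(alignment))
}

#' Partition a substrate group into clade-consistent subgroups
#'
#' Deterministic stand-in for delimiting clades by eye in a substrate
#' specific NJ tree: the tree is midpoint-rooted, the maximal subtrees whose
#' leaves all belong to the group become initial parts (group members
#' scattered as singletons are their own parts), and the smallest parts are
#' greedily merged with their topologically nearest part until at most
#' `max_parts` parts remain and every part has at least `min_part_size`
#' members. Ties are broken lexicographically on the smallest member id, so
#' the partition is invariant to leaf input order. A group smaller than
#' `2 * min_part_size` is returned as a single part flagged
#' `subdivided = FALSE`.
#'
#' @param tree An `ape::phylo` containing all group members as tips.
#' @param annotation Annotation `data.frame` (`seq_id`, `substrate`).
#' @param group Substrate code whose members are partitioned.
#' @param max_parts Maximum number of parts, 2-4 (default 4).
#' @param min_part_size Minimum members per part (default 3).
#' @return Object of class `clade_partition`: list with `group`,
#'   `subgroups` (list of id vectors), `subdivided` flag.
#' @export
substrate_subgroups <- function(tree, annotation, group, max_parts = 4L,
                                min_part_size = 3L) {
  if (max_parts < 2L || max_parts > 4L) stopf("max_parts must be 2-4")
  members <- sort(annotation$seq_id[annotation$substrate == group])
  if (length(members) == 0L) stopf("no members with substrate '%s'", group)
  miss <- setdiff(members, tree$tip.label)
  if (length(miss)) stopf("group member(s) missing from tree: %s",
                          paste(miss, collapse = ", "))
  if (length(members) < 2L * min_part_size) {
    return(structure(list(group = group, subgroups = list(members),
                          subdivided = FALSE), class = "clade_partition"))
  }
  rooted <- phangorn::midpoint(tree)
  parts <- maximal_pure_clades(rooted, members)
  # greedy merging on topological distance between part "centroids"
  topo <- ape::dist.nodes(topology_only(rooted))
  tips <- rooted$tip.label
  part_key <- function(p) min(p)
  repeat {
    sizes <- lengths(parts)
    need_merge <- length(parts) > max_parts ||
      (length(parts) > 1L && min(sizes) < min_part_size)
    if (!need_merge || length(parts) == 1L) break
    ord <- order(sizes, vapply(parts, part_key, ""))
    i <- ord[1L]
    # nearest other part: min over cross pairs of tip-tip topological distance
    best_j <- NA_integer_; best_d <- Inf; best_key <- ""
    for (j in seq_along(parts)) {
      if (j == i) next
      dd <- min(topo[match(parts[[i]], tips), match(parts[[j]], tips)])
      key <- part_key(parts[[j]])
      if (dd < best_d || (dd == best_d && key < best_key)) {
        best_d <- dd; best_j <- j; best_key <- key
      }
    }
    parts[[i]] <- sort(c(parts[[i]], parts[[best_j]]))
    parts[[best_j]] <- NULL
  }
  parts <- parts[order(vapply(parts, part_key, ""))]
  structure(list(group = group, subgroups = parts,
                 subdivided = length(parts) > 1L),
            class = "clade_partition")
}

# unit branch lengths so dist.nodes counts edges
topology_only <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

# maximal clades of a rooted tree whose tip sets lie entirely inside `members`
maximal_pure_clades <- function(rooted, members) {
  ntip <- length(rooted$tip.label)
  node_tips <- vector("list", ntip + rooted$Nnode)
  for (i in seq_len(ntip)) node_tips[[i]] <- rooted$tip.label[i]
  # postorder accumulation of descendant tips
  po <- ape::reorder.phylo(rooted, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; child <- po$edge[k, 2L]
    node_tips[[par]] <- c(node_tips[[par]], node_tips[[child]])
  }
  pure <- vapply(node_tips, function(tp) all(tp %in% members), logical(1))
  parent_of <- integer(ntip + rooted$Nnode)
  parent_of[rooted$edge[, 2L]] <- rooted$edge[, 1L]
  root <- ntip + 1L
  maximal <- which(vapply(seq_along(pure), function(nd) {
    pure[nd] && (nd == root || !pure[parent_of[nd]])
  }, logical(1)))
  parts <- lapply(maximal, function(nd) sort(node_tips[[nd]]))
  parts[order(vapply(parts, min, ""))]
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("Clade partition of '%s': %d part(s)%s\n", x$group,
              length(x$subgroups),
              if (!x$subdivided) " [not subdivided]" else ""))
  for (i in seq_along(x$subgroups)) {
    cat(sprintf("  part %d (n=%d): %s\n", i, length(x$subgroups[[i]]),
                paste(utils::head(x$subgroups[[i]], 6L), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape with 6-significant-digit branch lengths on write.
#'
#' @param path File path.
#' @return `read_newick()` returns an `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
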