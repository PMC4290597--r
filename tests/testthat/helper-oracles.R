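# Independent oracles and fixture builders shared across test files.
# These re-derive expected results by brute force or closed form and must
# stay independent of the implementation paths they check.

# ---- tree utilities --------------------------------------------------------

tree_parent_vec <- function(tree) {
  parent <- rep(NA_integer_, max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

tree_children_list <- function(tree) {
  kids <- vector("list", max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  }
  kids
}

ancestors_of <- function(parent, v) {
  out <- v
  while (!is.na(parent[out[length(out)]])) {
    out <- c(out, parent[out[length(out)]])
  }
  out
}

# ---- brute-force duplication/loss reconciliation ---------------------------
# Enumerates every valid species-node assignment for the gene tree's
# internal nodes (each must be an ancestor-or-equal of its children's
# images) and, per node, takes a speciation whenever the children's
# images fall into distinct child subtrees of the assigned node.
# Returns the minimum of (duplications + losses) and the event counts of
# a minimizing assignment.
brute_force_reconcile <- function(gene_tree, species_tree, leaf_map) {
  map <- stats::setNames(as.character(leaf_map$species_leaf),
                         as.character(leaf_map$gene_leaf))
  s_parent <- tree_parent_vec(species_tree)
  s_root <- which(is.na(s_parent))[1L]
  s_kids <- tree_children_list(species_tree)
  s_depth <- integer(length(s_parent))
  for (v in seq_along(s_parent)) {
    s_depth[v] <- length(ancestors_of(s_parent, v)) - 1L
  }
  s_anc <- lapply(seq_along(s_parent), function(v) ancestors_of(s_parent, v))
  is_anc_or_eq <- function(a, v) a %in% s_anc[[v]]

  g_parent <- tree_parent_vec(gene_tree)
  g_kids <- tree_children_list(gene_tree)
  g_ntip <- length(gene_tree$tip.label)
  g_root <- which(is.na(g_parent))[1L]
  g_depth <- integer(length(g_parent))
  for (v in seq_along(g_parent)) {
    g_depth[v] <- length(ancestors_of(g_parent, v)) - 1L
  }
  internal <- setdiff(order(g_depth, decreasing = TRUE), seq_len(g_ntip))

  M_leaf <- match(map[gene_tree$tip.label], species_tree$tip.label)
  assign_best <- list(total = Inf, dup = NA, loss = NA)

  count_events <- function(M) {
    dups <- 0L; losses <- 0L
    for (g in internal) {
      ch <- g_kids[[g]]
      m <- M[g]; m1 <- M[ch[1L]]; m2 <- M[ch[2L]]
      spec_ok <- FALSE
      if (m1 != m && m2 != m) {
        kid_sub <- vapply(s_kids[[m]], function(k) {
          is_anc_or_eq(k, m1) + 2L * is_anc_or_eq(k, m2)
        }, 0L)
        # speciation iff the two images sit under different children
        spec_ok <- any(kid_sub == 1L) && any(kid_sub == 2L)
      }
      if (spec_ok) {
        losses <- losses + (s_depth[m1] - s_depth[m] - 1L) +
          (s_depth[m2] - s_depth[m] - 1L)
      } else {
        dups <- dups + 1L
        losses <- losses +
          max(s_depth[m1] - s_depth[m], 0L) +
          max(s_depth[m2] - s_depth[m], 0L)
      }
    }
    list(dup = dups, loss = losses)
  }

  M <- rep(NA_integer_, max(gene_tree$edge))
  M[seq_len(g_ntip)] <- M_leaf
  recurse <- function(k) {
    if (k > length(internal)) {
      ev <- count_events(M)
      if (ev$dup + ev$loss < assign_best$total) {
        assign_best <<- list(total = ev$dup + ev$loss,
                             dup = ev$dup, loss = ev$loss)
      }
      return(invisible(NULL))
    }
    g <- internal[k]
    ch <- g_kids[[g]]
    # candidates: common ancestors of both children's images
    cand <- intersect(s_anc[[M[ch[1L]]]], s_anc[[M[ch[2L]]]])
    for (m in cand) {
      M[g] <<- m
      recurse(k + 1L)
    }
    M[g] <<- NA_integer_
  }
  recurse(1L)
  assign_best
}

# ---- brute-force NJ topology oracle ----------------------------------------
# Least-squares branch-length fit of a fixed topology to a distance
# matrix; the generating topology of an additive matrix fits with zero
# residual.
ls_fit_residual <- function(topology, d) {
  tips <- topology$tip.label
  n <- length(tips)
  pairs <- utils::combn(n, 2L)
  n_edges <- nrow(topology$edge)
  A <- matrix(0, ncol(pairs), n_edges)
  y <- numeric(ncol(pairs))
  edge_key <- paste(topology$edge[, 1L], topology$edge[, 2L])
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    path <- ape::nodepath(topology, i, j)
    for (s in seq_len(length(path) - 1L)) {
      e <- which(edge_key == paste(path[s], path[s + 1L]) |
                   edge_key == paste(path[s + 1L], path[s]))
      A[p, e] <- 1
    }
    y[p] <- d[tips[i], tips[j]]
  }
  fit <- stats::lsfit(A, y, intercept = FALSE)
  sum(fit$residuals^2)
}

best_topology_brute_force <- function(d) {
  n <- nrow(d)
  tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(d))
  resid <- vapply(tops, ls_fit_residual, 0, d = d)
  tops[[which.min(resid)]]
}

same_unrooted_topology <- function(t1, t2) {
  isTRUE(all.equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1L], 0))
}

# random additive distance matrix from a random binary tree
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  D <- ape::dist.nodes(tr)[seq_len(n), seq_len(n)]
  dimnames(D) <- list(tr$tip.label, tr$tip.label)
  list(tree = tr, d = D)
}

# ---- misc fixtures ---------------------------------------------------------

make_proteins <- function(ids, lengths = 600L, genome_id = "g1") {
  data.frame(protein_id = ids, genome_id = genome_id,
             sequence = vapply(lengths + integer(length(ids)), function(n)
               paste(rep("A", n), collapse = ""), ""),
             length = lengths + integer(length(ids)),
             stringsAsFactors = FALSE)
}

make_annotations <- function(protein_id, accessions) {
  if (length(accessions) == 0L) {
    return(data.frame(protein_id = character(), accession = character(),
                      description = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- 10L + (seq_along(accessions) - 1L) * 100L
  data.frame(protein_id = protein_id, accession = accessions,
             description = "", start = start, end = start + 79L,
             stringsAsFactors = FALSE)
}

# independent re-count of family assignments straight from the annotation
# table (no call into the classifier's per-protein loop)
brute_force_family_count <- function(proteins, annotations, profile) {
  sum(vapply(proteins$protein_id, function(pid) {
    acc <- annotations$accession[annotations$protein_id == pid]
    all(vapply(profile$clauses, function(cl) {
      sum(table(acc)[names(table(acc)) %in% cl$alternatives]) >= cl$min_hits
    }, TRUE))
  }, TRUE))
}
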