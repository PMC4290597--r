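# Alignment-free composition-vector distances, neighbor joining,
# rooting, and LCA gene-tree/species-tree reconciliation.

# ---- composition vectors ---------------------------------------------------

.kmer_freq <- function(sequences, k) {
  windows <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }), use.names = FALSE)
  if (length(windows) == 0L) return(NULL)
  tab <- table(windows)
  stats::setNames(as.numeric(tab) / length(windows), names(tab))
}

#' Composition vector of a proteome
#'
#' Counts all overlapping K-strings within each protein (no cross-protein
#' windows), normalizes to frequencies `f`, and subtracts a (K-2)-order
#' Markov background: `f0(a1..aK) = f(a1..aK-1) * f(a2..aK) / f(a2..aK-1)`,
#' each factor a frequency among windows of its own length. The score of
#' an observed K-string is `(f - f0) / f0`, or 0 where `f0 = 0`. K = 7 is
#' the default, the tuple length known to work well for fungal phylogeny.
#'
#' @param proteome Data frame from [parse_fasta()], or a character vector
#'   of ungapped protein sequences.
#' @param K Tuple length, at least 3 (the background needs K-1 and K-2
#'   strings).
#' @param genome_id Label carried on the vector (defaults to the
#'   proteome's `genome_id` when present).
#' @return Object of class `composition_vector`: `genome_id`, `K`, and
#'   `scores` (named sparse numeric vector over observed K-strings).
#' @export
composition_vector <- function(proteome, K = 7L, genome_id = NULL) {
  K <- as.integer(K)
  if (K < 3L) stop("K must be at least 3")
  if (is.data.frame(proteome)) {
    if (is.null(genome_id)) genome_id <- proteome$genome_id[1L]
    sequences <- proteome$sequence
  } else {
    sequences <- as.character(proteome)
  }
  if (length(sequences) == 0L) stop("empty proteome")
  sequences <- toupper(sequences)
  fK <- .kmer_freq(sequences, K)
  if (is.null(fK)) {
    stop("no sequence is at least K = ", K, " residues long")
  }
  f1 <- .kmer_freq(sequences, K - 1L)
  f2 <- .kmer_freq(sequences, K - 2L)
  kmers <- names(fK)
  pre <- substr(kmers, 1L, K - 1L)
  suf <- substr(kmers, 2L, K)
  mid <- substr(kmers, 2L, K - 1L)
  f0 <- unname(f1[pre]) * unname(f1[suf]) / unname(f2[mid])
  f0[!is.finite(f0)] <- 0
  score <- ifelse(f0 > 0, (unname(fK) - f0) / f0, 0)
  structure(list(genome_id = if (is.null(genome_id)) NA_character_ else
                   genome_id,
                 K = K,
                 scores = stats::setNames(score, kmers)),
            class = "composition_vector")
}

#' Composition-vector distance between two proteomes
#'
#' Cosine similarity `C` over the union of the two score supports (absent
#' K-strings contribute 0), mapped to a distance `D = (1 - C) / 2` in
#' \[0, 1\].
#'
#' @param u,v `composition_vector` objects with the same `K`.
#' @return Non-negative distance.
#' @export
cv_distance <- function(u, v) {
  stopifnot(inherits(u, "composition_vector"),
            inherits(v, "composition_vector"))
  if (u$K != v$K) stop("composition vectors have different K")
  keys <- union(names(u$scores), names(v$scores))
  x <- stats::setNames(numeric(length(keys)), keys)
  y <- x
  x[names(u$scores)] <- u$scores
  y[names(v$scores)] <- v$scores
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("cosine undefined for an all-zero composition vector")
  }
  C <- sum(x * y) / (nx * ny)
  max((1 - C) / 2, 0)
}

#' Pairwise composition-vector distance matrix
#'
#' @param vectors List of `composition_vector` objects with distinct
#'   genome ids.
#' @return Symmetric numeric matrix with genome-id dimnames.
#' @export
cv_distance_matrix <- function(vectors) {
  labs <- vapply(vectors, `[[`, "", "genome_id")
  if (anyDuplicated(labs)) stop("duplicate genome ids among vectors")
  n <- length(vectors)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- cv_distance(vectors[[i]], vectors[[j]])
    }
  }
  d
}

# ---- alignment distances ---------------------------------------------------

#' p-distance matrix from an alignment
#'
#' Pairwise proportion of differing residues over columns where both rows
#' are ungapped. A pair with no comparable column is an error.
#'
#' @param alignment Named character vector of gapped rows.
#' @return Symmetric matrix with row-name dimnames.
#' @export
p_distance_matrix <- function(alignment) {
  alignment <- as_alignment(alignment)
  if (length(alignment) < 2L) stop("need at least 2 rows")
  chars <- .aln_chars(alignment)
  n <- nrow(chars)
  labs <- names(alignment)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- chars[i, ] != "-" & chars[j, ] != "-"
    if (!any(ok)) {
      stop("no comparable columns between '", labs[i], "' and '",
           labs[j], "'")
    }
    d[i, j] <- d[j, i] <- mean(chars[i, ok] != chars[j, ok])
  }
  d
}

# ---- neighbor joining ------------------------------------------------------

.check_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance input must be a square matrix")
  }
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  }
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix has a non-zero diagonal")
  }
  if (any(!is.finite(d)) || any(d < -1e-12)) {
    stop("distances must be finite and non-negative")
  }
  d
}

.bl <- function(x) sprintf("%.17g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with the Studier-Keppler Q-criterion.
#' Negative branch lengths arising from non-additive input are clamped to
#' 0 with the deficit transferred to the sister branch, preserving the
#' pair's summed length. On an additive matrix the generating topology and
#' branch lengths are recovered exactly. Ties in the Q-criterion are
#' broken by the first (row-major) minimal pair, so results are
#' deterministic.
#'
#' @param d Symmetric distance matrix (zero diagonal) with at least 3
#'   labels; a `dist` object is accepted.
#' @return Unrooted [ape::phylo] tree (basal trifurcation).
#' @export
neighbor_joining <- function(d) {
  d <- .check_dist_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 labels")
  node_str <- rownames(d)
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_str <- paste0("(", node_str[i], ":", .bl(bi), ",",
                      node_str[j], ":", .bl(bj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    node_str <- c(node_str[keep], new_str)
    dimnames(d) <- list(seq_len(n - 1L), seq_len(n - 1L))
    n <- n - 1L
  }
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  cc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", node_str[1L], ":", .bl(max(a, 0)), ",",
                node_str[2L], ":", .bl(max(b, 0)), ",",
                node_str[3L], ":", .bl(max(cc, 0)), ");")
  ape::read.tree(text = txt)
}

# ---- rooting ---------------------------------------------------------------

# adjacency list (node -> data.frame(to, len)) from a phylo edge matrix
.tree_adjacency <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_nodes <- max(tree$edge)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, len = len))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, len = len))
  }
  adj
}

.subtree_newick <- function(adj, labels, node, parent) {
  nb <- adj[[node]]
  kids <- nb[nb$to != parent, , drop = FALSE]
  if (nrow(kids) == 0L) return(labels[node])
  inner <- vapply(seq_len(nrow(kids)), function(k) {
    paste0(.subtree_newick(adj, labels, kids$to[k], node), ":",
           .bl(kids$len[k]))
  }, "")
  paste0("(", paste(inner, collapse = ","), ")")
}

# root an unrooted tree on the edge (u, v), at distance x from u
.root_on_edge <- function(tree, u, v, x) {
  adj <- .tree_adjacency(tree)
  labels <- character(max(tree$edge))
  labels[seq_along(tree$tip.label)] <- tree$tip.label
  eu <- adj[[u]]
  len_uv <- eu$len[eu$to == v][1L]
  left <- paste0(.subtree_newick(adj, labels, u, v), ":", .bl(x))
  right <- paste0(.subtree_newick(adj, labels, v, u), ":",
                  .bl(len_uv - x))
  ape::read.tree(text = paste0("(", left, ",", right, ");"))
}

#' Midpoint rooting
#'
#' Roots an unrooted tree at the midpoint of the longest leaf-to-leaf
#' path. Ties on the path length are broken by the lexicographically
#' smallest (sorted) leaf-label pair, making the result deterministic.
#'
#' @param tree Unrooted [ape::phylo] with branch lengths.
#' @return Rooted [ape::phylo].
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("branch lengths required")
  ntip <- length(tree$tip.label)
  if (ntip == 2L) {
    h <- sum(tree$edge.length) / 2
    labs <- sort(tree$tip.label)
    return(ape::read.tree(text = paste0("(", labs[1L], ":", .bl(h), ",",
                                        labs[2L], ":", .bl(h), ");")))
  }
  D <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip), drop = FALSE]
  dmax <- max(D)
  cand <- which(D >= dmax - 1e-12 & upper.tri(D), arr.ind = TRUE)
  keys <- apply(cand, 1L, function(ij) {
    paste(sort(tree$tip.label[ij]), collapse = "\r")
  })
  pick <- cand[order(keys)[1L], ]
  best <- list(i = pick[1L], j = pick[2L])
  half <- D[best$i, best$j] / 2
  path <- ape::nodepath(tree, best$i, best$j)
  adj <- .tree_adjacency(tree)
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    eu <- adj[[u]]
    len <- eu$len[eu$to == v][1L]
    if (cum + len >= half - 1e-12) {
      x <- min(max(half - cum, 0), len)
      return(.root_on_edge(tree, u, v, x))
    }
    cum <- cum + len
  }
  stop("internal error: midpoint not located on the longest path")
}

# ---- reconciliation --------------------------------------------------------

.tree_children <- function(tree) {
  n_nodes <- max(tree$edge)
  kids <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]],
                                  tree$edge[e, 2L])
  }
  kids
}

.tree_parent <- function(tree) {
  n_nodes <- max(tree$edge)
  parent <- rep(NA_integer_, n_nodes)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

.node_depths <- function(parent, root) {
  depth <- rep(NA_integer_, length(parent))
  depth[root] <- 0L
  repeat {
    todo <- which(is.na(depth) & !is.na(parent) & !is.na(depth[parent]))
    if (length(todo) == 0L) break
    depth[todo] <- depth[parent[todo]] + 1L
  }
  depth
}

#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the species LCA of its mapped leaf
#' descendants. An internal gene node is a duplication iff its mapping
#' equals the mapping of at least one child; otherwise it is a
#' speciation. Losses along the child edge from gene node `g` to child
#' `c` number `depth(M(c)) - depth(M(g)) - 1`, plus one more when `g` is
#' a duplication and `M(c) != M(g)`. This LCA mapping is the most
#' parsimonious duplication/loss reconciliation.
#'
#' @param gene_tree Rooted binary [ape::phylo].
#' @param species_tree Rooted binary [ape::phylo].
#' @param leaf_map Data frame with columns `gene_leaf`, `species_leaf`, or
#'   a named character vector (names = gene leaves).
#' @return List of class `reconciliation_summary`: `events` (data frame:
#'   `gene_node`, `event`, `species_node`, `species_label`, `losses`),
#'   `n_duplications`, `n_losses`, `loss_by_branch` (named integer, losses
#'   attributed to the species branch above each node), and `per_leaf`
#'   (data frame of duplication/loss counts attributable to terminal
#'   species branches).
#' @export
reconcile_lca <- function(gene_tree, species_tree, leaf_map) {
  for (nm in c("gene", "species")) {
    tr <- if (nm == "gene") gene_tree else species_tree
    if (!ape::is.rooted(tr)) stop(nm, " tree must be rooted")
    if (!ape::is.binary(tr)) stop(nm, " tree must be binary")
  }
  if (is.data.frame(leaf_map)) {
    map <- stats::setNames(as.character(leaf_map$species_leaf),
                           as.character(leaf_map$gene_leaf))
  } else {
    map <- leaf_map
  }
  g_tips <- gene_tree$tip.label
  if (!all(g_tips %in% names(map))) {
    stop("unmapped gene leaf(s): ",
         paste(setdiff(g_tips, names(map)), collapse = ", "))
  }
  if (!all(map[g_tips] %in% species_tree$tip.label)) {
    stop("leaf map targets unknown species leaf(s): ",
         paste(setdiff(map[g_tips], species_tree$tip.label),
               collapse = ", "))
  }

  s_ntip <- length(species_tree$tip.label)
  s_parent <- .tree_parent(species_tree)
  s_root <- which(is.na(s_parent))[1L]
  s_depth <- .node_depths(s_parent, s_root)
  s_kids <- .tree_children(species_tree)
  s_anc <- lapply(seq_along(s_parent), function(v) {
    path <- v
    while (!is.na(s_parent[path[length(path)]])) {
      path <- c(path, s_parent[path[length(path)]])
    }
    path
  })
  s_lca <- function(a, b) {
    if (a == b) return(a)
    common <- intersect(s_anc[[a]], s_anc[[b]])
    common[which.max(s_depth[common])]
  }
  s_label <- function(v) {
    if (v <= s_ntip) species_tree$tip.label[v] else paste0("node_", v)
  }

  g_ntip <- length(g_tips)
  g_parent <- .tree_parent(gene_tree)
  g_root <- which(is.na(g_parent))[1L]
  g_kids <- .tree_children(gene_tree)
  n_gnodes <- max(gene_tree$edge)

  M <- rep(NA_integer_, n_gnodes)
  M[seq_len(g_ntip)] <- match(map[g_tips], species_tree$tip.label)
  # postorder over internal nodes by decreasing depth from the root
  g_depth <- .node_depths(g_parent, g_root)
  internal <- setdiff(order(g_depth, decreasing = TRUE), seq_len(g_ntip))
  loss_by_branch <- stats::setNames(integer(length(s_parent)),
                                    vapply(seq_along(s_parent), s_label, ""))
  dup_by_node <- integer(length(s_parent))
  events <- data.frame(gene_node = integer(), event = character(),
                       species_node = integer(), species_label = character(),
                       losses = integer(), stringsAsFactors = FALSE)
  for (g in internal) {
    ch <- g_kids[[g]]
    M[g] <- s_lca(M[ch[1L]], M[ch[2L]])
    is_dup <- any(M[ch] == M[g])
    node_losses <- 0L
    for (c1 in ch) {
      # species path p[1] = M(g), ..., p[k+1] = M(c1)
      p <- rev(s_anc[[M[c1]]])
      p <- p[seq.int(match(M[g], p), length(p))]
      k <- length(p) - 1L
      if (k == 0L) next
      # the lineage descends step t: p[t] -> p[t+1]; the sibling child of
      # p[t] loses it, except at t = 1 after a speciation (the speciation
      # itself sends the other gene child there)
      start_t <- if (is_dup) 1L else 2L
      if (k < start_t) next
      for (t in start_t:k) {
        sib <- setdiff(s_kids[[p[t]]], p[t + 1L])
        loss_by_branch[sib] <- loss_by_branch[sib] + 1L
        node_losses <- node_losses + 1L
      }
    }
    if (is_dup) dup_by_node[M[g]] <- dup_by_node[M[g]] + 1L
    events <- rbind(events, data.frame(
      gene_node = g,
      event = if (is_dup) "duplication" else "speciation",
      species_node = M[g], species_label = s_label(M[g]),
      losses = node_losses, stringsAsFactors = FALSE))
  }
  total_losses <- sum(loss_by_branch)
  per_leaf <- data.frame(
    species_leaf = species_tree$tip.label,
    duplications = dup_by_node[seq_len(s_ntip)],
    losses = as.integer(loss_by_branch[seq_len(s_ntip)]),
    stringsAsFactors = FALSE)
  structure(list(events = events,
                 mapping = M,
                 n_duplications = sum(events$event == "duplication"),
                 n_losses = as.integer(total_losses),
                 loss_by_branch = loss_by_branch,
                 dup_by_species = stats::setNames(
                   dup_by_node, vapply(seq_along(s_parent), s_label, "")),
                 per_leaf = per_leaf),
            class = "reconciliation_summary")
}

#' @export
print.reconciliation_summary <- function(x, ...) {
  cat("<reconciliation_summary> duplications:", x$n_duplications,
      " losses:", x$n_losses, "\n")
  invisible(x)
}

#' Root a gene tree to minimize duplications plus losses
#'
#' Tries a root on every edge of the unrooted gene tree, reconciles each
#' candidate against the species tree, and returns the rooted tree with
#' the smallest duplication + loss total (first minimal edge in edge-matrix
#' order on ties).
#'
#' @param gene_tree Unrooted [ape::phylo] with branch lengths.
#' @param species_tree,leaf_map As in [reconcile_lca()].
#' @return List with `tree` (rooted phylo), `summary`
#'   (`reconciliation_summary`) and `score`.
#' @export
root_min_dl <- function(gene_tree, species_tree, leaf_map) {
  best <- NULL
  for (e in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[e, 1L]; v <- gene_tree$edge[e, 2L]
    len <- gene_tree$edge.length[e]
    cand <- .root_on_edge(gene_tree, u, v, len / 2)
    rec <- tryCatch(reconcile_lca(cand, species_tree, leaf_map),
                    error = function(err) NULL)
    if (is.null(rec)) next
    score <- rec$n_duplications + rec$n_losses
    if (is.null(best) || score < best$score) {
      best <- list(tree = cand, summary = rec, score = score)
    }
  }
  if (is.null(best)) stop("no rooting produced a valid reconciliation")
  best
}
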