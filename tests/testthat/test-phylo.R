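# Composition vectors, distances, tree building, rooting, reconciliation.

test_that("composition vectors match the hand-computed Markov background", {
  # single sequence AAAA, K = 3: one distinct 3-string, f = 1,
  # f0 = f(AA) * f(AA) / f(A) = 1, score (1 - 1)/1 = 0
  cv <- composition_vector("AAAA", K = 3)
  expect_equal(names(cv$scores), "AAA")
  expect_equal(unname(cv$scores), 0)

  # two-letter sequence, K = 3: windows AB,BA of length 2 etc.
  # hand computation for "ABAB": 3-strings ABA, BAB each f = 1/2;
  # 2-strings AB (2/3), BA (1/3); 1-strings A, B each 1/2.
  # f0(ABA) = f(AB) * f(BA) / f(B) = (2/3)(1/3)/(1/2) = 4/9
  # score(ABA) = (1/2 - 4/9)/(4/9) = 1/8
  cv2 <- composition_vector("ABAB", K = 3)
  expect_equal(unname(cv2$scores["ABA"]), (1 / 2 - 4 / 9) / (4 / 9),
               tolerance = 1e-12)

  # determinism: identical proteomes give identical vectors
  p <- c("MKLVNDAQWERT", "GGHHIIKKLLMM")
  expect_identical(composition_vector(p, K = 4)$scores,
                   composition_vector(p, K = 4)$scores)

  # sequences shorter than K contribute no windows
  cv3 <- composition_vector(c("AAAA", "GG"), K = 3)
  expect_equal(names(cv3$scores), "AAA")

  expect_error(composition_vector("AAAA", K = 2), "at least 3")
  expect_error(composition_vector(c("AB", "CD"), K = 3), "residues long")
})

test_that("composition-vector distances satisfy identity, symmetry and range", {
  set.seed(31)
  mk <- function(id) {
    composition_vector(
      vapply(1:3, function(i)
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40, TRUE),
              collapse = ""), ""),
      K = 3, genome_id = id)
  }
  u <- mk("u"); v <- mk("v")
  expect_equal(cv_distance(u, u), 0)
  expect_equal(cv_distance(u, v), cv_distance(v, u))
  expect_gte(cv_distance(u, v), 0)
  expect_lte(cv_distance(u, v), 1)

  # disjoint K-string support with non-negative scores -> D = 0.5
  a <- structure(list(genome_id = "a", K = 3L,
                      scores = c(AAA = 1, CCC = 2)),
                 class = "composition_vector")
  b <- structure(list(genome_id = "b", K = 3L,
                      scores = c(DDD = 3, EEE = 1)),
                 class = "composition_vector")
  expect_equal(cv_distance(a, b), 0.5)

  zero <- structure(list(genome_id = "z", K = 3L, scores = c(AAA = 0)),
                    class = "composition_vector")
  expect_error(cv_distance(a, zero), "all-zero")
  expect_error(cv_distance(a, composition_vector("AAAAA", K = 4)),
               "different K")
})

test_that("p-distances count differing residues over mutually ungapped columns", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"],
               0.25)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "A-AA", b = "AGAT"))["a", "b"],
               1 / 3)
  expect_error(p_distance_matrix(c(a = "A-", b = "-A")), "comparable")
  expect_error(p_distance_matrix(c(a = "AA")), "at least 2")
})

test_that("neighbor joining solves the three-point formulas exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
})

test_that("neighbor joining recovers additive trees exactly", {
  for (n in c(4L, 5L, 7L)) {
    gen <- random_additive_matrix(n, seed = 100 + n)
    tr <- neighbor_joining(gen$d)
    expect_true(same_unrooted_topology(tr, gen$tree))
    # reconstructed path lengths reproduce the input matrix
    D2 <- ape::dist.nodes(tr)[seq_len(n), seq_len(n)]
    dimnames(D2) <- list(tr$tip.label, tr$tip.label)
    expect_equal(D2[rownames(gen$d), colnames(gen$d)], gen$d,
                 tolerance = 1e-9)
  }
})

test_that("neighbor joining is invariant to label permutation and validates input", {
  gen <- random_additive_matrix(5L, seed = 9)
  perm <- sample(5L)
  tr1 <- neighbor_joining(gen$d)
  tr2 <- neighbor_joining(gen$d[perm, perm])
  expect_true(same_unrooted_topology(tr1, tr2))

  bad <- gen$d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(neighbor_joining(bad), "symmetric")
  bad2 <- gen$d; diag(bad2)[2] <- 0.5
  expect_error(neighbor_joining(bad2), "diagonal")
  expect_error(neighbor_joining(gen$d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining agrees with the reference implementation on noisy matrices", {
  set.seed(17)
  for (rep in 1:3) {
    gen <- random_additive_matrix(6L, seed = 200 + rep)
    noise <- matrix(runif(36, 0, 0.02), 6)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    d <- gen$d + noise
    expect_true(same_unrooted_topology(neighbor_joining(d),
                                       ape::nj(as.dist(d))))
  }
})

test_that("midpoint rooting halves the longest leaf-to-leaf path", {
  two <- parse_newick("(A:1,B:3);")
  mp2 <- midpoint_root(two)
  expect_equal(sort(mp2$edge.length), c(2, 2))

  # symmetric quartet roots on the central edge
  sym <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  mp <- midpoint_root(ape::unroot(sym))
  expect_true(ape::is.rooted(mp))
  depths <- ape::node.depth.edgelength(mp)
  expect_equal(max(depths[1:4]) - min(depths[1:4]), 0)

  gen <- random_additive_matrix(6L, seed = 55)
  mp6 <- midpoint_root(gen$tree)
  D <- ape::dist.nodes(gen$tree)[1:6, 1:6]
  h <- ape::node.depth.edgelength(mp6)[1:6]
  expect_equal(max(h), max(D) / 2, tolerance = 1e-9)

  expect_error(midpoint_root(ape::read.tree(text = "(A,B,C);")),
               "branch lengths")
})

test_that("midpoint ties break on the lexicographically smallest leaf pair", {
  # two leaf pairs at equal maximal distance: (B,Z) and (A,Z) both 4;
  # sorted pairs A|Z < B|Z so the root must sit midway on the A-Z path
  tr <- parse_newick("((A:2,B:2):1,Z:1);")
  mp <- midpoint_root(ape::unroot(tr))
  h <- setNames(ape::node.depth.edgelength(mp)[1:3], mp$tip.label)
  expect_equal(unname(h["A"]), 2)
  expect_equal(unname(h["Z"]), 2)
})

test_that("LCA reconciliation reproduces the canonical event counts", {
  st <- parse_newick("((A:1,B:1):1,C:2);")

  congruent <- reconcile_lca(
    parse_newick("((a:1,b:1):1,c:2);"), st,
    data.frame(gene_leaf = c("a", "b", "c"),
               species_leaf = c("A", "B", "C")))
  expect_equal(congruent$n_duplications, 0L)
  expect_equal(congruent$n_losses, 0L)

  st2 <- parse_newick("(A:1,B:1);")
  dup <- reconcile_lca(
    parse_newick("((a1:1,a2:1):1,b:2);"), st2,
    data.frame(gene_leaf = c("a1", "a2", "b"),
               species_leaf = c("A", "A", "B")))
  expect_equal(dup$n_duplications, 1L)
  expect_equal(dup$n_losses, 0L)
  expect_equal(dup$per_leaf$duplications[dup$per_leaf$species_leaf == "A"],
               1L)

  loss <- reconcile_lca(
    parse_newick("(a:1,c:1);"), st,
    data.frame(gene_leaf = c("a", "c"), species_leaf = c("A", "C")))
  expect_equal(loss$n_duplications, 0L)
  expect_equal(loss$n_losses, 1L)
  expect_equal(loss$per_leaf$losses[loss$per_leaf$species_leaf == "B"], 1L)
})

test_that("reconciliation validates rooting, binarity and the leaf map", {
  st <- parse_newick("((A:1,B:1):1,C:2);")
  gt <- parse_newick("(a:1,c:1);")
  expect_error(reconcile_lca(parse_newick("((a:1,b:1,c:1):1,d:1);"), st,
                             data.frame(gene_leaf = c("a", "b", "c", "d"),
                                        species_leaf = c("A", "B", "C",
                                                         "C"))),
               "binary")
  expect_error(reconcile_lca(gt, st,
                             data.frame(gene_leaf = "a",
                                        species_leaf = "A")),
               "unmapped")
  expect_error(reconcile_lca(gt, st,
                             data.frame(gene_leaf = c("a", "c"),
                                        species_leaf = c("A", "Q"))),
               "unknown species")
})

test_that("reconciliation totals are invariant to child-order permutation", {
  st <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  gt <- parse_newick("(((a1:1,b:1):1,a2:1):1,(c:1,d:1):1);")
  lm <- data.frame(gene_leaf = c("a1", "b", "a2", "c", "d"),
                   species_leaf = c("A", "B", "A", "C", "D"))
  r1 <- reconcile_lca(gt, st, lm)
  gt_rot <- parse_newick("((d:1,c:1):1,((b:1,a1:1):1,a2:1):1);")
  st_rot <- parse_newick("((D:1,C:1):1,(B:1,A:1):1);")
  r2 <- reconcile_lca(gt_rot, st_rot, lm)
  expect_equal(r2$n_duplications, r1$n_duplications)
  expect_equal(r2$n_losses, r1$n_losses)
})

test_that("LCA reconciliation attains the brute-force event minimum", {
  st <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  set.seed(23)
  species <- c("A", "B", "C", "D")
  for (rep in 1:12) {
    n_genes <- sample(3:6, 1)
    gt <- ape::rtree(n_genes, tip.label = paste0("g", seq_len(n_genes)))
    lm <- data.frame(gene_leaf = gt$tip.label,
                     species_leaf = sample(species, n_genes,
                                           replace = TRUE))
    got <- reconcile_lca(gt, st, lm)
    oracle <- brute_force_reconcile(gt, st, lm)
    expect_equal(got$n_duplications + got$n_losses, oracle$total)
    expect_equal(got$n_duplications, oracle$dup)
    expect_equal(got$n_losses, oracle$loss)
  }
})

test_that("duplication-minimizing rooting never beats the best edge by exhaustion", {
  st <- parse_newick("((A:1,B:1):1,C:2);")
  gt_unrooted <- ape::unroot(
    parse_newick("((a1:1,c1:1):1,(a2:1,b1:1):1);"))
  lm <- data.frame(gene_leaf = c("a1", "c1", "a2", "b1"),
                   species_leaf = c("A", "C", "A", "B"))
  best <- root_min_dl(gt_unrooted, st, lm)
  # exhaustive score over every edge rooting equals the reported score
  scores <- vapply(seq_len(nrow(gt_unrooted$edge)), function(e) {
    u <- gt_unrooted$edge[e, 1]; v <- gt_unrooted$edge[e, 2]
    cand <- rnaikit:::.root_on_edge(gt_unrooted, u, v,
                                    gt_unrooted$edge.length[e] / 2)
    r <- reconcile_lca(cand, st, lm)
    r$n_duplications + r$n_losses
  }, 0)
  expect_equal(best$score, min(scores))
})
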