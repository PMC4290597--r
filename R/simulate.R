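# Seeded generators for synthetic inputs: proteomes with planted domain
# architectures, and birth-death gene-family histories along a species
# tree. Outputs are deterministic given the seed, and each generator
# returns the planted truth so downstream inference can be checked
# exactly.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.random_seq <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

# accession pool for background proteins; deliberately disjoint from every
# default-profile accession so planted truth is unambiguous
.background_pool <- c("IPR001650", "IPR014001", "IPR011545", "IPR006935",
                      "IPR014720", "IPR000719", "IPR011009", "IPR002290",
                      "IPR013087", "IPR020635")

.profile_hit_plan <- list(
  Argonaute = c("IPR003100", "IPR003165"),
  Dicer = c("IPR000999", "IPR000999", "IPR005034"),
  RdRP = "IPR007855"
)

.place_hits <- function(protein_id, accessions, hit_width = 80L,
                        gap = 50L) {
  if (length(accessions) == 0L) {
    return(data.frame(protein_id = character(), accession = character(),
                      description = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- 10L + (seq_along(accessions) - 1L) * (hit_width + gap)
  data.frame(protein_id = protein_id, accession = accessions,
             description = "synthetic domain", start = start,
             end = start + hit_width - 1L, stringsAsFactors = FALSE)
}

#' Generate a proteome with planted domain architectures
#'
#' Planted family members carry exactly the hits that satisfy the default
#' profiles (an Argonaute gets one PAZ and one Piwi hit; a Dicer gets two
#' RNase III hits plus one dsRNA-binding hit; an RdRP one polymerase hit).
#' Background proteins carry either random accessions drawn from a pool
#' disjoint from all profile accessions, or near-miss architectures (a
#' single RNase III hit with a dsRNA-binding domain, PAZ without Piwi,
#' Piwi without PAZ) that must be rejected by a correct classifier.
#' Sequences are random residues; the default length of 600 aa clears the
#' 500-aa evaluation filter. Hits are placed non-overlapping left to
#' right. Regenerating with the same seed reproduces identical records.
#'
#' @param n_background Number of background (non-family) proteins.
#' @param family_counts Named integer vector of planted members per family
#'   (names among `Argonaute`, `Dicer`, `RdRP`).
#' @param seed Integer seed.
#' @param genome_id Genome identifier for all records.
#' @param seq_length Residue length of every generated sequence.
#' @return List with `proteins` (data frame as from [parse_fasta()]),
#'   `annotations` (as from [parse_interpro_tsv()]) and `truth` (list:
#'   `seed`, `planted_counts`, `planted_ids`).
#' @examples
#' sim <- gen_annotated_proteome(5, c(Argonaute = 2, RdRP = 1), seed = 1)
#' classify_proteome(sim$proteins, sim$annotations)$counts
#' @export
gen_annotated_proteome <- function(n_background,
                                   family_counts = c(Argonaute = 0L,
                                                     Dicer = 0L,
                                                     RdRP = 0L),
                                   seed = 1L,
                                   genome_id = "synthetic_genome",
                                   seq_length = 600L) {
  stopifnot(n_background >= 0L, all(family_counts >= 0L))
  unknown <- setdiff(names(family_counts), names(.profile_hit_plan))
  if (length(unknown)) {
    stop("no planting plan for family(ies): ",
         paste(unknown, collapse = ", "))
  }
  .with_seed(seed, {
    proteins <- list()
    annotations <- list()
    planted_ids <- list()
    idx <- 0L
    for (fam in names(family_counts)) {
      ids <- character(0)
      for (k in seq_len(family_counts[[fam]])) {
        idx <- idx + 1L
        pid <- sprintf("SIM_%s_%03d", toupper(substr(fam, 1L, 4L)), k)
        ids <- c(ids, pid)
        proteins[[length(proteins) + 1L]] <-
          data.frame(protein_id = pid, genome_id = genome_id,
                     sequence = .random_seq(seq_length),
                     length = seq_length, stringsAsFactors = FALSE)
        annotations[[length(annotations) + 1L]] <-
          .place_hits(pid, .profile_hit_plan[[fam]])
      }
      planted_ids[[fam]] <- ids
    }
    near_miss <- list(c("IPR000999", "IPR005034"),   # single RNase III
                      "IPR003100",                   # PAZ without Piwi
                      "IPR003165")                   # Piwi without PAZ
    for (k in seq_len(n_background)) {
      pid <- sprintf("SIM_BG_%03d", k)
      proteins[[length(proteins) + 1L]] <-
        data.frame(protein_id = pid, genome_id = genome_id,
                   sequence = .random_seq(seq_length),
                   length = seq_length, stringsAsFactors = FALSE)
      acc <- if (stats::runif(1) < 0.4) {
        near_miss[[sample.int(length(near_miss), 1L)]]
      } else {
        sample(.background_pool, sample.int(3L, 1L))
      }
      annotations[[length(annotations) + 1L]] <- .place_hits(pid, acc)
    }
    proteins <- if (length(proteins)) do.call(rbind, proteins) else
      data.frame(protein_id = character(), genome_id = character(),
                 sequence = character(), length = integer(),
                 stringsAsFactors = FALSE)
    annotations <- do.call(rbind, c(annotations,
                                    list(.place_hits("x", character()))))
    rownames(proteins) <- rownames(annotations) <- NULL
    list(proteins = proteins, annotations = annotations,
         truth = list(seed = seed,
                      planted_counts = family_counts,
                      planted_ids = planted_ids))
  })
}

#' Write a generated proteome as FASTA + TSV fixture files
#'
#' @param sim Result of [gen_annotated_proteome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_fixture_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteome.fasta")
  tsv <- file.path(dir, "annotations.tsv")
  write_fasta(sim$proteins, fasta)
  utils::write.table(sim$annotations, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta, annotations = tsv))
}

#' Simulate a birth-death gene-family history on a species tree
#'
#' A single ancestral gene enters at the species root and evolves along
#' the species tree: duplications (rate `dup_rate` per unit branch
#' length) split a lineage in two, losses (rate `loss_rate`) kill it, and
#' at each speciation every surviving lineage enters both daughter
#' branches. The observable gene tree keeps only lineages with surviving
#' descendants (unifurcations suppressed), so some true events are
#' invisible; parsimony reconciliation of the observable tree can
#' therefore never infer more events than the recorded truth. If fewer
#' than two gene copies survive, the replicate is regenerated from the
#' next seed substream (reported in `truth$attempts`).
#'
#' @param species_tree Rooted binary [ape::phylo] with branch lengths.
#' @param dup_rate,loss_rate Non-negative event rates per unit branch
#'   length.
#' @param seed Integer seed.
#' @param max_tries Maximum regeneration attempts before failing.
#' @return List with `gene_tree` (rooted [ape::phylo]), `leaf_map` (data
#'   frame `gene_leaf`, `species_leaf`) and `truth` (list: `seed`,
#'   `attempts`, `n_duplications`, `n_losses`, `dup_by_branch`,
#'   `loss_by_branch` named by species node).
#' @export
gen_family_history <- function(species_tree, dup_rate, loss_rate,
                               seed = 1L, max_tries = 100L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  if (!ape::is.rooted(species_tree) || !ape::is.binary(species_tree)) {
    stop("species tree must be rooted and binary")
  }
  if (is.null(species_tree$edge.length)) {
    stop("species tree must have branch lengths")
  }
  s_parent <- .tree_parent(species_tree)
  s_root <- which(is.na(s_parent))[1L]
  s_kids <- .tree_children(species_tree)
  s_ntip <- length(species_tree$tip.label)
  blen <- stats::setNames(rep(NA_real_, length(s_parent)),
                          seq_along(s_parent))
  blen[species_tree$edge[, 2L]] <- species_tree$edge.length
  node_name <- vapply(seq_along(s_parent), function(v) {
    if (v <= s_ntip) species_tree$tip.label[v] else paste0("node_", v)
  }, "")

  for (attempt in seq_len(max_tries)) {
    env <- new.env()
    env$dup <- stats::setNames(integer(length(s_parent)), node_name)
    env$loss <- env$dup
    env$leaf_counter <- stats::setNames(integer(s_ntip),
                                        species_tree$tip.label)
    res <- .with_seed(seed + attempt - 1L, {
      sim_lineage <- function(sp, remaining) {
        lam <- dup_rate + loss_rate
        if (lam > 0) {
          w <- stats::rexp(1L, lam)
          if (w < remaining) {
            if (stats::runif(1L) < dup_rate / lam) {
              env$dup[sp] <- env$dup[sp] + 1L
              left <- sim_lineage(sp, remaining - w)
              right <- sim_lineage(sp, remaining - w)
              if (is.null(left)) return(right)
              if (is.null(right)) return(left)
              return(list(kind = "node", left = left, right = right))
            }
            env$loss[sp] <- env$loss[sp] + 1L
            return(NULL)
          }
        }
        if (sp <= s_ntip) {
          lab <- species_tree$tip.label[sp]
          env$leaf_counter[lab] <- env$leaf_counter[lab] + 1L
          return(list(kind = "leaf",
                      name = paste0(lab, "_g", env$leaf_counter[lab]),
                      species = lab))
        }
        ch <- s_kids[[sp]]
        left <- sim_lineage(ch[1L], blen[ch[1L]])
        right <- sim_lineage(ch[2L], blen[ch[2L]])
        if (is.null(left)) return(right)
        if (is.null(right)) return(left)
        list(kind = "node", left = left, right = right)
      }
      sim_lineage(s_root, 0)
    })
    n_leaves <- .count_gene_leaves(res)
    if (n_leaves >= 2L) {
      nwk <- paste0(.gene_newick(res), ";")
      gt <- ape::read.tree(text = nwk)
      leaves <- .collect_gene_leaves(res)
      return(list(
        gene_tree = gt,
        leaf_map = data.frame(gene_leaf = names(leaves),
                              species_leaf = unname(leaves),
                              stringsAsFactors = FALSE),
        truth = list(seed = seed, attempts = attempt,
                     n_duplications = sum(env$dup),
                     n_losses = sum(env$loss),
                     dup_by_branch = env$dup,
                     loss_by_branch = env$loss)))
    }
  }
  stop("all gene lineages went extinct in ", max_tries, " attempts; ",
       "lower loss_rate or raise max_tries")
}

.count_gene_leaves <- function(node) {
  if (is.null(node)) return(0L)
  if (node$kind == "leaf") return(1L)
  .count_gene_leaves(node$left) + .count_gene_leaves(node$right)
}

.gene_newick <- function(node) {
  if (node$kind == "leaf") return(paste0(node$name, ":1"))
  paste0("(", .gene_newick(node$left), ",", .gene_newick(node$right),
         "):1")
}

.collect_gene_leaves <- function(node) {
  if (node$kind == "leaf") {
    return(stats::setNames(node$species, node$name))
  }
  c(.collect_gene_leaves(node$left), .collect_gene_leaves(node$right))
}
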