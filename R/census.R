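# Per-taxon census summaries, group comparisons, and accessory-domain
# analysis of Dicer architectures.

#' Per-genome gene-family counts
#'
#' Counts, for every genome in the taxonomy table, how many proteins carry
#' each family in their classification call. Genomes present in the
#' taxonomy but absent from the calls contribute zero counts; genomes in
#' the calls but missing a lineage are an error.
#'
#' @param calls Calls data frame (from [classify_proteome()]`$calls` or
#'   [read_calls_tsv()]).
#' @param taxonomy Data frame from [read_taxonomy()].
#' @param families Families to tabulate; defaults to all families occurring
#'   in the calls.
#' @return Data frame: `genome_id`, then one integer column per family.
#' @export
per_genome_counts <- function(calls, taxonomy, families = NULL) {
  missing_lineage <- setdiff(unique(calls$genome_id), taxonomy$genome_id)
  if (length(missing_lineage)) {
    stop("genome(s) without taxonomy lineage: ",
         paste(missing_lineage, collapse = ", "))
  }
  fam_lists <- strsplit(calls$families, ",", fixed = TRUE)
  if (is.null(families)) {
    families <- sort(setdiff(unique(unlist(fam_lists)), ""))
  }
  out <- data.frame(genome_id = taxonomy$genome_id, stringsAsFactors = FALSE)
  for (f in families) {
    has <- vapply(fam_lists, function(x) f %in% x, TRUE)
    tab <- table(factor(calls$genome_id[has], levels = taxonomy$genome_id))
    out[[f]] <- as.integer(tab)
  }
  out
}

#' Taxon-level census of gene-family counts
#'
#' Summarizes per-genome counts at a chosen taxonomic level. Each row
#' reports, per family, the mean gene count per genome (2 decimals), the
#' min and max, and a formatted `"mean (min-max)"` cell; genomes with zero
#' predicted genes are included in the means.
#'
#' @param calls,taxonomy,families As in [per_genome_counts()].
#' @param level One of `"kingdom"`, `"phylum"`, `"subphylum"`: the depth of
#'   grouping (subphylum groups by the full kingdom/phylum/subphylum key).
#' @return Data frame with the lineage key columns, `n_genomes`, and per
#'   family columns `<fam>_mean`, `<fam>_min`, `<fam>_max`, `<fam>_summary`.
#' @examples
#' # two genomes in one subphylum with Argonaute counts 2 and 3 -> "2.50 (2-3)"
#' @export
taxon_summary <- function(calls, taxonomy,
                          level = c("kingdom", "phylum", "subphylum"),
                          families = NULL) {
  level <- match.arg(level)
  counts <- per_genome_counts(calls, taxonomy, families)
  families <- setdiff(names(counts), "genome_id")
  keys <- switch(level,
                 kingdom = "kingdom",
                 phylum = c("kingdom", "phylum"),
                 subphylum = c("kingdom", "phylum", "subphylum"))
  tax <- taxonomy[match(counts$genome_id, taxonomy$genome_id), , drop = FALSE]
  grp <- do.call(interaction,
                 c(unname(as.list(tax[keys])),
                   list(drop = TRUE, lex.order = TRUE, sep = "\r")))
  rows <- lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    key_vals <- as.list(tax[idx[1L], keys, drop = FALSE])
    row <- c(key_vals, list(n_genomes = length(idx)))
    for (f in families) {
      x <- counts[[f]][idx]
      row[[paste0(f, "_mean")]] <- round(mean(x), 2)
      row[[paste0(f, "_min")]] <- min(x)
      row[[paste0(f, "_max")]] <- max(x)
      row[[paste0(f, "_summary")]] <-
        sprintf("%.2f (%d-%d)", mean(x), min(x), max(x))
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test on per-genome counts
#'
#' Two-sided, unequal-variance (Welch) comparison of two groups of
#' per-genome gene counts. When both groups have zero variance and equal
#' means the test is degenerate and `t = 0`, `p = 1` is returned by
#' contract; zero variance in both groups with different means is an
#' error (the statistic is unbounded).
#'
#' @param counts_a,counts_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `p` and `df`.
#' @export
group_t_test <- function(counts_a, counts_b) {
  if (length(counts_a) < 2L || length(counts_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  va <- stats::var(counts_a)
  vb <- stats::var(counts_b)
  if (va == 0 && vb == 0) {
    if (mean(counts_a) == mean(counts_b)) {
      return(list(t = 0, p = 1, df = NA_real_))
    }
    stop("zero variance in both groups with unequal means: ",
         "t statistic undefined")
  }
  tt <- stats::t.test(counts_a, counts_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Accessory (non-essential) domain analysis for a gene family
#'
#' For every classified protein, the accessory domains are the distinct
#' annotated accessions minus the family profile's essential accessions.
#' Reports the per-protein accessory-domain counts, a presence/absence
#' matrix, per-accession prevalence, and mean accessory-domain counts
#' overall and per taxonomic group when a taxonomy is supplied.
#'
#' @param calls Calls data frame restricted to the family of interest
#'   (e.g. rows whose `families` include `"Dicer"`).
#' @param annotations Annotation data frame joinable by `protein_id`.
#' @param profile The family's [family_profile] (supplies the essential
#'   accession set).
#' @param taxonomy Optional [read_taxonomy()] table for group means.
#' @param level Grouping level when `taxonomy` is given.
#' @return List with `matrix` (logical protein x accession presence),
#'   `per_protein` (data frame `protein_id`, `n_additional`),
#'   `prevalence` (data frame `accession`, `n`, `pct`, `label` like
#'   `"50.00% (1 of 2)"`), `mean_additional`, and `group_means` (or `NULL`).
#' @export
auxiliary_domains <- function(calls, annotations, profile,
                              taxonomy = NULL, level = "kingdom") {
  ess <- profile$essential_accessions
  ann <- annotations[annotations$protein_id %in% calls$protein_id, ,
                     drop = FALSE]
  acc_by_pid <- split(ann$accession, ann$protein_id)
  extra <- lapply(calls$protein_id, function(pid) {
    setdiff(unique(acc_by_pid[[pid]]), ess)
  })
  names(extra) <- calls$protein_id
  all_extra <- sort(unique(unlist(extra)))
  mat <- matrix(FALSE, nrow = nrow(calls), ncol = length(all_extra),
                dimnames = list(calls$protein_id, all_extra))
  for (i in seq_along(extra)) mat[i, extra[[i]]] <- TRUE
  n_add <- vapply(extra, length, 0L)
  n_prot <- nrow(calls)
  prev_n <- if (length(all_extra)) colSums(mat) else integer()
  prevalence <- data.frame(
    accession = all_extra,
    n = as.integer(prev_n),
    pct = round(100 * prev_n / n_prot, 2),
    label = sprintf("%.2f%% (%d of %d)", 100 * prev_n / n_prot,
                    as.integer(prev_n), n_prot),
    stringsAsFactors = FALSE)
  rownames(prevalence) <- NULL
  group_means <- NULL
  if (!is.null(taxonomy)) {
    tax <- taxonomy[match(calls$genome_id, taxonomy$genome_id), ,
                    drop = FALSE]
    grp <- tax[[level]]
    group_means <- vapply(split(n_add, grp), function(x)
      round(mean(x), 2), 0)
  }
  list(matrix = mat,
       per_protein = data.frame(protein_id = calls$protein_id,
                                n_additional = unname(n_add),
                                stringsAsFactors = FALSE),
       prevalence = prevalence,
       mean_additional = round(mean(n_add), 2),
       group_means = group_means)
}

#' Write a presence/absence matrix with O/X symbols
#'
#' `O` marks presence of the accession on a protein, `X` absence.
#'
#' @param mat Logical matrix (proteins x accessions).
#' @param path Output path.
#' @export
write_presence_absence <- function(mat, path) {
  sym <- ifelse(mat, "O", "X")
  tab <- data.frame(protein_id = rownames(mat), sym, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
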