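# Domain-architecture profiles and proteome classification.
#
# A family profile is a conjunction of requirement clauses; each clause is
# satisfied when the total number of annotation hits whose accession falls
# in the clause's alternative set reaches min_hits. Hit counting is per
# annotation row: overlapping hits for the same accession count separately,
# which is what makes the "at least two RNase III domains" rule for Dicer
# expressible.

#' Construct a family profile
#'
#' @param family Family name (e.g. `"Argonaute"`).
#' @param clauses List of clauses; each clause is a list with
#'   `alternatives` (non-empty character vector of InterPro accessions) and
#'   `min_hits` (positive integer). All clauses must hold for a protein to
#'   be assigned the family.
#' @return An object of class `family_profile` with fields `family`,
#'   `clauses` and `essential_accessions` (union of all alternatives).
#' @export
family_profile <- function(family, clauses) {
  if (length(clauses) == 0L) stop("profile needs at least one clause")
  clauses <- lapply(clauses, function(cl) {
    alt <- as.character(cl$alternatives)
    mh <- as.integer(cl$min_hits)
    if (length(alt) == 0L) stop("clause with empty alternative set")
    if (any(!grepl("^IPR[0-9]{6}$", alt))) {
      stop("clause alternatives must be IPR accessions, got: ",
           paste(alt[!grepl("^IPR[0-9]{6}$", alt)], collapse = ", "))
    }
    if (is.na(mh) || mh < 1L) stop("min_hits must be a positive integer")
    list(alternatives = alt, min_hits = mh)
  })
  structure(list(family = as.character(family), clauses = clauses,
                 essential_accessions =
                   unique(unlist(lapply(clauses, `[[`, "alternatives")))),
            class = "family_profile")
}

#' @export
print.family_profile <- function(x, ...) {
  cat("<family_profile> ", x$family, "\n", sep = "")
  for (cl in x$clauses) {
    cat("  {", paste(cl$alternatives, collapse = " | "), "} >= ",
        cl$min_hits, "\n", sep = "")
  }
  invisible(x)
}

#' Default domain profiles for the RNAi core machinery
#'
#' Argonaute requires the PAZ domain (IPR003100) and the Piwi domain
#' (IPR003165). Dicer requires at least two Ribonuclease III hits
#' (IPR000999) plus one double-stranded RNA-binding domain (IPR001159 or
#' IPR005034); proteins with a single RNase III hit are thereby discarded.
#' RdRP requires the eukaryotic RNA-dependent RNA polymerase domain
#' (IPR007855).
#'
#' @param require_dsrbd If `FALSE`, drop the dsRNA-binding clause from the
#'   Dicer profile. Non-fungal Dicers sometimes lack the domain, so the
#'   clause can be relaxed per run; it is required by default.
#' @return Named list of [family_profile] objects
#'   (`Argonaute`, `Dicer`, `RdRP`).
#' @examples
#' default_profiles()$Dicer
#' @export
default_profiles <- function(require_dsrbd = TRUE) {
  dicer_clauses <- list(list(alternatives = "IPR000999", min_hits = 2L))
  if (require_dsrbd) {
    dicer_clauses <- c(dicer_clauses,
                       list(list(alternatives = c("IPR001159", "IPR005034"),
                                 min_hits = 1L)))
  }
  list(
    Argonaute = family_profile("Argonaute", list(
      list(alternatives = "IPR003100", min_hits = 1L),
      list(alternatives = "IPR003165", min_hits = 1L))),
    Dicer = family_profile("Dicer", dicer_clauses),
    RdRP = family_profile("RdRP", list(
      list(alternatives = "IPR007855", min_hits = 1L)))
  )
}

#' Derive a profile from reference annotations
#'
#' Builds a single-accession clause (`{a} >= 1`) for every accession
#' carried by at least `share_threshold` of the reference proteins, and
#' returns the full share table so a curator can merge interchangeable
#' accessions into OR-clauses afterwards.
#'
#' @param family_name Name for the derived profile.
#' @param reference_annotations Named list: protein id -> character vector
#'   of accessions carried by that reference protein.
#' @param share_threshold Fraction in (0, 1]; accessions present in at
#'   least this fraction of references enter the profile.
#' @return List with `profile` ([family_profile]) and `share_table`
#'   (named numeric: accession -> fraction of references carrying it).
#' @export
build_profile_from_references <- function(family_name, reference_annotations,
                                          share_threshold = 1.0) {
  if (length(reference_annotations) == 0L) {
    stop("no reference proteins supplied")
  }
  if (share_threshold <= 0 || share_threshold > 1) {
    stop("share_threshold must be in (0, 1]")
  }
  per_ref <- lapply(reference_annotations, unique)
  share <- table(unlist(per_ref)) / length(per_ref)
  share <- sort(unclass(share), decreasing = TRUE)
  keep <- names(share)[share >= share_threshold - 1e-12]
  if (length(keep) == 0L) {
    stop("no accession reaches the share threshold ", share_threshold)
  }
  clauses <- lapply(keep, function(a) list(alternatives = a, min_hits = 1L))
  list(profile = family_profile(family_name, clauses),
       share_table = share)
}

.clause_hits <- function(accessions, clause) {
  sum(accessions %in% clause$alternatives)
}

#' Classify one protein against a set of family profiles
#'
#' A family is assigned iff every one of its clauses is satisfied: the
#' total hit count over the clause's alternative accessions reaches
#' `min_hits`. Several families may match; unknown accessions simply never
#' match.
#'
#' @param protein A list or one-row data frame with `protein_id` and
#'   `genome_id`.
#' @param annotations Data frame of annotations for this protein (as from
#'   [parse_interpro_tsv()]); rows for other proteins are an error.
#' @param profiles Named list of [family_profile] objects.
#' @return Object of class `classification_call`: `protein_id`,
#'   `genome_id`, `families` (character vector of matched family names) and
#'   `evidence` (per family, the integer vector of per-clause matched hit
#'   counts).
#' @export
classify_protein <- function(protein, annotations, profiles = default_profiles()) {
  pid <- protein$protein_id
  if (nrow(annotations) > 0L && any(annotations$protein_id != pid)) {
    stop("annotations reference a different protein than ", pid)
  }
  acc <- annotations$accession
  evidence <- lapply(profiles, function(p) {
    vapply(p$clauses, function(cl) .clause_hits(acc, cl), 0L)
  })
  matched <- vapply(seq_along(profiles), function(i) {
    mins <- vapply(profiles[[i]]$clauses, `[[`, 0L, "min_hits")
    all(evidence[[i]] >= mins)
  }, TRUE)
  structure(list(protein_id = pid,
                 genome_id = protein$genome_id,
                 families = names(profiles)[matched],
                 evidence = evidence),
            class = "classification_call")
}

.encode_evidence <- function(evidence) {
  paste(vapply(names(evidence), function(f) {
    paste0(f, "=", paste(evidence[[f]], collapse = "/"))
  }, ""), collapse = ";")
}

#' Classify a whole proteome
#'
#' Applies [classify_protein()] to every protein record. Annotations
#' referencing unknown protein ids are dropped with a warning. When
#' `min_length` is set, proteins shorter than that many residues are
#' excluded before classification (the length filter is off by default;
#' it is always applied in recall evaluation).
#'
#' @param proteins Data frame from [parse_fasta()].
#' @param annotations Data frame from [parse_interpro_tsv()].
#' @param profiles Named list of [family_profile] objects.
#' @param min_length Residue-count cutoff, or `NULL` for no filter.
#' @return List with `calls` (data frame: `protein_id`, `genome_id`,
#'   `families` comma-separated, `evidence` encoded text) and `counts`
#'   (named integer vector: per family, the number of proteins whose call
#'   includes that family; a protein matching two profiles counts in both).
#' @export
classify_proteome <- function(proteins, annotations,
                              profiles = default_profiles(),
                              min_length = NULL) {
  unknown <- setdiff(unique(annotations$protein_id), proteins$protein_id)
  if (length(unknown)) {
    warning("ignoring annotations for unknown protein id(s): ",
            paste(unknown, collapse = ", "))
    annotations <- annotations[!annotations$protein_id %in% unknown, ,
                               drop = FALSE]
  }
  if (!is.null(min_length)) {
    proteins <- proteins[proteins$length >= min_length, , drop = FALSE]
  }
  ann_by_pid <- split(annotations$accession, annotations$protein_id)
  fam_names <- names(profiles)
  mins <- lapply(profiles, function(p)
    vapply(p$clauses, `[[`, 0L, "min_hits"))
  fam_col <- character(nrow(proteins))
  evi_col <- character(nrow(proteins))
  counts <- stats::setNames(integer(length(profiles)), fam_names)
  for (i in seq_len(nrow(proteins))) {
    acc <- ann_by_pid[[proteins$protein_id[i]]]
    if (is.null(acc)) acc <- character()
    evidence <- lapply(profiles, function(p)
      vapply(p$clauses, function(cl) .clause_hits(acc, cl), 0L))
    names(evidence) <- fam_names
    hit <- vapply(fam_names, function(f)
      all(evidence[[f]] >= mins[[f]]), TRUE)
    fam_col[i] <- paste(fam_names[hit], collapse = ",")
    evi_col[i] <- .encode_evidence(evidence)
    counts[hit] <- counts[hit] + 1L
  }
  list(calls = data.frame(protein_id = proteins$protein_id,
                          genome_id = proteins$genome_id,
                          families = fam_col,
                          evidence = evi_col,
                          stringsAsFactors = FALSE),
       counts = counts)
}

#' Evaluate classifier recall on a labeled test set
#'
#' The denominator is the set of labeled proteins passing the length
#' filter (default 500 aa, reflecting that the reference sequences behind
#' the profiles average roughly 900-1600 aa); the numerator is the subset
#' whose classification call contains the true family. Recall is reported
#' as a percentage rounded to two decimals; an empty denominator yields
#' `NA` (undefined), never 0.
#'
#' @param labels Named character vector: protein id -> true family name.
#' @param proteins,annotations,profiles As in [classify_proteome()].
#' @param min_length Length cutoff applied to the labeled set.
#' @return List with `overall` (pooled recall %), `per_family` (named
#'   numeric %), `n_evaluated` and `n_captured`.
#' @export
evaluate_recall <- function(labels, proteins, annotations,
                            profiles = default_profiles(),
                            min_length = 500L) {
  if (length(labels) == 0L) stop("empty test set")
  missing_ids <- setdiff(names(labels), proteins$protein_id)
  if (length(missing_ids)) {
    stop("labeled protein id(s) absent from proteins: ",
         paste(missing_ids, collapse = ", "))
  }
  res <- classify_proteome(proteins, annotations, profiles,
                           min_length = NULL)
  calls <- res$calls
  len <- stats::setNames(proteins$length, proteins$protein_id)
  keep <- names(labels)[len[names(labels)] >= min_length]
  fam_of <- stats::setNames(strsplit(calls$families, ",", fixed = TRUE),
                            calls$protein_id)
  captured <- vapply(keep, function(pid) {
    labels[[pid]] %in% fam_of[[pid]]
  }, TRUE)
  pct <- function(num, den) if (den == 0L) NA_real_ else
    round(100 * num / den, 2)
  fams <- unique(unname(labels))
  per_family <- vapply(fams, function(f) {
    ids <- keep[labels[keep] == f]
    pct(sum(captured[ids]), length(ids))
  }, 0)
  list(overall = pct(sum(captured), length(keep)),
       per_family = per_family,
       n_evaluated = length(keep),
       n_captured = sum(captured))
}
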