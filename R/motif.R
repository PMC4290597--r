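# Alignment-anchored catalytic-motif extraction, DDH variant
# classification, column conservation scoring and logo frequency matrices.
#
# All operations anchor on a reference row: positions are stated in the
# ungapped coordinate system of the reference sequence (e.g. the QDE-2
# catalytic triad for Argonautes, or QDE-1 double-psi beta-barrel residues
# for RdRPs) and mapped onto alignment columns by walking the gapped
# reference row.

.aln_chars <- function(alignment) {
  alignment <- as_alignment(alignment)
  do.call(rbind, strsplit(unclass(alignment), "", fixed = TRUE))
}

#' Map ungapped reference positions to alignment columns
#'
#' Column `i` of the result is the alignment column holding the
#' reference's `i`-th requested residue; gaps in the reference row are
#' skipped while counting.
#'
#' @param alignment Named character vector of gapped rows
#'   ([as_alignment()]).
#' @param reference_id Name of the reference row.
#' @param reference_positions Ordered 1-based positions in the ungapped
#'   reference sequence.
#' @return Integer vector of alignment column indices.
#' @examples
#' aln <- c(ref = "D-DH", x = "DADH")
#' map_reference_columns(aln, "ref", c(1, 2, 3))  # 1 3 4
#' @export
map_reference_columns <- function(alignment, reference_id,
                                  reference_positions) {
  alignment <- as_alignment(alignment)
  if (!reference_id %in% names(alignment)) {
    stop("reference '", reference_id, "' absent from alignment")
  }
  chars <- strsplit(alignment[[reference_id]], "", fixed = TRUE)[[1L]]
  ungapped_cols <- which(chars != "-")
  pos <- as.integer(reference_positions)
  if (any(pos < 1L) || any(pos > length(ungapped_cols))) {
    stop("reference position out of range 1..", length(ungapped_cols))
  }
  ungapped_cols[pos]
}

#' Classify a catalytic-triad residue triple
#'
#' Categories follow the Argonaute slicer-motif variant scheme: the
#' canonical Asp-Asp-His triad; the experimentally relaxed third residue
#' DD\[HDEK\]; a conserved DD with any other third residue; everything
#' else; and `missing` when any anchored column carries a gap.
#'
#' @param residues Character vector of exactly three residue letters or
#'   `"-"`.
#' @return One of `"conserved_DDH"`, `"H_sub_DEK"`, `"H_sub_other"`,
#'   `"other_variant"`, `"missing"`.
#' @export
classify_ddh_variant <- function(residues) {
  residues <- toupper(as.character(residues))
  if (length(residues) != 3L) stop("expected a triple of residues")
  if (any(residues == "-")) return("missing")
  if (identical(residues, c("D", "D", "H"))) return("conserved_DDH")
  if (residues[1L] == "D" && residues[2L] == "D") {
    if (residues[3L] %in% c("D", "E", "K")) return("H_sub_DEK")
    return("H_sub_other")
  }
  "other_variant"
}

#' Extract anchored catalytic residues for every aligned sequence
#'
#' Reads the residues at the mapped reference columns for each
#' non-reference row and assigns the variant category with
#' [classify_ddh_variant()].
#'
#' @inheritParams map_reference_columns
#' @return Data frame: `sequence_id`, `residues` (collapsed letters, `-`
#'   for gaps), `category`.
#' @export
extract_motif <- function(alignment, reference_id, reference_positions) {
  alignment <- as_alignment(alignment)
  cols <- map_reference_columns(alignment, reference_id,
                                reference_positions)
  chars <- .aln_chars(alignment)
  rows <- setdiff(names(alignment), reference_id)
  res <- vapply(rows, function(r) {
    paste(chars[match(r, names(alignment)), cols], collapse = "")
  }, "")
  cat <- vapply(rows, function(r) {
    classify_ddh_variant(strsplit(res[[r]], "", fixed = TRUE)[[1L]])
  }, "")
  data.frame(sequence_id = rows, residues = unname(res),
             category = unname(cat), stringsAsFactors = FALSE,
             row.names = NULL)
}

.ddh_categories <- c("conserved_DDH", "H_sub_DEK", "H_sub_other",
                     "other_variant", "missing")

#' Per-taxon distribution of motif variant categories
#'
#' @param calls Data frame from [extract_motif()].
#' @param seq_genome Named character vector: sequence id -> genome id.
#' @param taxonomy [read_taxonomy()] table.
#' @param level Grouping level (`"kingdom"`, `"phylum"`, `"subphylum"`).
#' @return Data frame: one row per non-empty group, `group`, `n`, then one
#'   proportion column per category (rows sum to 1; `missing` is its own
#'   slice).
#' @export
motif_distribution <- function(calls, seq_genome, taxonomy,
                               level = "kingdom") {
  gid <- seq_genome[calls$sequence_id]
  if (any(is.na(gid))) {
    stop("sequence(s) without genome mapping: ",
         paste(calls$sequence_id[is.na(gid)], collapse = ", "))
  }
  grp <- taxonomy[[level]][match(gid, taxonomy$genome_id)]
  if (any(is.na(grp))) {
    stop("genome(s) without taxonomy lineage: ",
         paste(unique(gid[is.na(grp)]), collapse = ", "))
  }
  rows <- lapply(sort(unique(grp)), function(g) {
    cats <- calls$category[grp == g]
    prop <- as.numeric(table(factor(cats, levels = .ddh_categories))) /
      length(cats)
    out <- data.frame(group = g, n = length(cats), stringsAsFactors = FALSE)
    out[.ddh_categories] <- as.list(prop)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Column conservation at anchored reference positions
#'
#' For every anchored column, the conservation fraction is the share of
#' all rows (reference included) whose residue equals the reference
#' residue (`mode = "match_reference"`, the default) or the modal non-gap
#' residue (`mode = "modal"`). Gaps always count in the denominator and
#' never match. Columns with conservation at or above `threshold` are
#' flagged ("70% or higher" is flagged at the default).
#'
#' @inheritParams map_reference_columns
#' @param threshold Flagging threshold in (0, 1].
#' @param mode `"match_reference"` or `"modal"`.
#' @return Data frame: `column` (alignment column), `ref_position`,
#'   `ref_residue`, `consensus_residue`, `fraction`, `flagged`.
#' @export
column_conservation <- function(alignment, reference_id,
                                reference_positions, threshold = 0.70,
                                mode = c("match_reference", "modal")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  alignment <- as_alignment(alignment)
  cols <- map_reference_columns(alignment, reference_id,
                                reference_positions)
  chars <- .aln_chars(alignment)
  ref_row <- match(reference_id, names(alignment))
  n <- nrow(chars)
  rows <- lapply(seq_along(cols), function(i) {
    col <- chars[, cols[i]]
    ref_res <- chars[ref_row, cols[i]]
    target <- if (mode == "match_reference") {
      ref_res
    } else {
      nong <- col[col != "-"]
      if (length(nong) == 0L) "-" else
        names(sort(table(nong), decreasing = TRUE))[1L]
    }
    frac <- if (target == "-") 0 else sum(col == target) / n
    data.frame(column = cols[i],
               ref_position = as.integer(reference_positions[i]),
               ref_residue = ref_res,
               consensus_residue = target,
               fraction = frac,
               flagged = frac >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residue frequency matrix for sequence-logo rendering
#'
#' Per alignment column in `column_range`, the frequency of each of the 20
#' standard residues plus the gap character; any additional letters
#' observed (ambiguity codes) get their own rows so each column still sums
#' to 1. The output is the numeric table a logo renderer consumes.
#'
#' @param alignment Named character vector of gapped rows.
#' @param column_range Integer vector of alignment columns (e.g. `5:40`).
#' @return Numeric matrix, rows = residue letters (20 aa, `-`, extras),
#'   columns = alignment columns.
#' @export
logo_matrix <- function(alignment, column_range) {
  alignment <- as_alignment(alignment)
  column_range <- as.integer(column_range)
  if (length(column_range) == 0L) stop("empty column range")
  if (any(column_range < 1L) ||
      any(column_range > attr(alignment, "n_columns"))) {
    stop("column range outside alignment width 1..",
         attr(alignment, "n_columns"))
  }
  chars <- .aln_chars(alignment)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  extras <- setdiff(sort(unique(as.vector(chars[, column_range,
                                                drop = FALSE]))),
                    c(aa20, "-"))
  letters_all <- c(aa20, "-", extras)
  m <- vapply(column_range, function(j) {
    as.numeric(table(factor(chars[, j], levels = letters_all))) /
      nrow(chars)
  }, numeric(length(letters_all)))
  dimnames(m) <- list(letters_all, as.character(column_range))
  m
}

.merge_intervals_span <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0L
  cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Drop proteins whose family-defining domain region is too short
#'
#' Sums the residue span of hits for the family's defining accessions
#' (overlapping hits merged) and retains only proteins whose merged span
#' reaches `min_domain_span`. Used e.g. to exclude truncated RdRPs whose
#' polymerase domain covers only a few dozen residues before alignment
#' analysis.
#'
#' @param calls Calls data frame (rows to filter).
#' @param annotations Annotation data frame joinable by `protein_id`.
#' @param accessions Defining accession(s) of the family.
#' @param min_domain_span Minimum merged span in residues (positive).
#' @return The retained subset of `calls`.
#' @export
filter_short_domain <- function(calls, annotations, accessions,
                                min_domain_span) {
  if (min_domain_span <= 0) stop("min_domain_span must be positive")
  keep <- vapply(calls$protein_id, function(pid) {
    hits <- annotations[annotations$protein_id == pid &
                          annotations$accession %in% accessions, ,
                        drop = FALSE]
    if (nrow(hits) == 0L) return(FALSE)
    .merge_intervals_span(hits$start, hits$end) >= min_domain_span
  }, TRUE)
  calls[keep, , drop = FALSE]
}
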