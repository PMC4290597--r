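# Readers and writers for the plain-text formats the toolkit consumes:
# protein FASTA (gapped or ungapped), InterProScan TSV, taxonomy tables,
# aligned FASTA, Newick trees, profile configs and PHYLIP-style matrices.

#' Parse a protein FASTA file or text
#'
#' Reads protein records from FASTA-formatted input. Sequences are
#' uppercased and line wrapping is irrelevant; record order is preserved.
#' The 20-residue alphabet plus the ambiguity codes X/B/Z/U (and `*`) is
#' accepted.
#'
#' @param source Path to a FASTA file, or a character vector of FASTA text
#'   (a single string with embedded newlines, or one element per line).
#' @param genome_id Genome identifier attached to every record. Protein ids
#'   are unique within a genome; ids may repeat across genomes.
#' @return A data frame with columns `protein_id`, `genome_id`, `sequence`
#'   and `length` (residue count), one row per record.
#' @examples
#' parse_fasta(c(">p1", "MKAD", "ef"), genome_id = "g1")
#' @export
parse_fasta <- function(source, genome_id = NA_character_) {
  lines <- .read_source_lines(source)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(protein_id = character(), genome_id = character(),
                      sequence = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA parse error at line ", first,
         ": sequence data before any '>' header")
  }
  set <- .biostrings_from_lines(lines)
  seqs <- toupper(as.character(set))
  ids <- vapply(names(set), function(h) strsplit(h, "[ \t]")[[1]][1L], "")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXBZU*]", gsub("[-.]", "", seqs))
  if (any(bad)) {
    stop("FASTA parse error: unexpected residue letters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  out <- data.frame(protein_id = unname(ids), genome_id = genome_id,
                    sequence = unname(seqs),
                    length = unname(nchar(gsub("[-.]", "", seqs))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.read_source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(unlist(strsplit(as.character(source), "\n", fixed = TRUE),
                        use.names = FALSE))
  }
}

.biostrings_from_lines <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  Biostrings::readAAStringSet(tf)
}

#' Write protein records as FASTA
#'
#' @param records Data frame with `protein_id` and `sequence` columns (as
#'   returned by [parse_fasta()]).
#' @param path Output file path.
#' @param width Wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$protein_id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Parse InterProScan tab-separated annotations
#'
#' Accepts either the 11+-column InterProScan 5 layout (protein id in
#' column 1, match coordinates in columns 7-8, InterPro accession and
#' description in columns 12-13) or a minimal 5-column layout
#' (`protein_id`, `accession`, `description`, `start`, `end`). The layout
#' is detected by locating the column carrying IPR-pattern accessions.
#' Rows without an integrated InterPro accession (empty or `-`) are
#' skipped. Coordinates are 1-based inclusive.
#'
#' @param source Path to a TSV file or character vector of TSV text.
#' @return A data frame with columns `protein_id`, `accession`,
#'   `description`, `start`, `end`, one row per retained annotation.
#' @export
parse_interpro_tsv <- function(source) {
  empty <- data.frame(protein_id = character(), accession = character(),
                      description = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  lines <- .read_source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(fields, length, 0L)
  ipr_col <- .detect_ipr_column(fields)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < ipr_col || !grepl("^IPR[0-9]{6}$", f[ipr_col])) return(NULL)
    if (ipr_col == 2L) {
      if (length(f) < 5L) {
        stop("InterPro TSV parse error at line ", i, ": expected 5 columns")
      }
      out <- list(id = f[1L], acc = f[2L], desc = f[3L],
                  start = f[4L], end = f[5L])
    } else {
      out <- list(id = f[1L], acc = f[ipr_col],
                  desc = if (length(f) >= ipr_col + 1L) f[ipr_col + 1L] else "",
                  start = f[7L], end = f[8L])
    }
    if (!grepl("^-?[0-9]+$", out$start) || !grepl("^-?[0-9]+$", out$end)) {
      stop("InterPro TSV parse error at line ", i,
           ": non-integer coordinate '", out$start, "'..'", out$end, "'")
    }
    s <- as.integer(out$start); e <- as.integer(out$end)
    if (s < 1L || s > e) {
      stop("InterPro TSV parse error at line ", i,
           ": invalid interval ", s, "..", e)
    }
    data.frame(protein_id = out$id, accession = out$acc,
               description = out$desc, start = s, end = e,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# The minimal layout carries the accession in column 2; InterProScan 5
# integrates it at column 12 (sometimes later when optional columns are
# present). Rows lacking an integrated accession carry "-" there.
.detect_ipr_column <- function(fields) {
  for (f in fields) {
    hit <- which(grepl("^IPR[0-9]{6}$", f))
    if (length(hit)) {
      # a minimal row has the accession in column 2; scan-native rows
      # place signature accessions earlier, so take the last match
      return(if (max(hit) == 2L || length(f) <= 5L) 2L else max(hit))
    }
  }
  2L
}

#' Read a taxonomy lineage table
#'
#' Expects a TSV with header `genome_id`, `kingdom`, `phylum`, `subphylum`.
#' `N/D` marks undetermined phylum or subphylum.
#'
#' @param source Path or character text.
#' @return Data frame with the four lineage columns.
#' @export
read_taxonomy <- function(source) {
  lines <- .read_source_lines(source)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("genome_id", "kingdom", "phylum", "subphylum")
  if (!all(need %in% names(tab))) {
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(tab$kingdom) | is.na(tab$kingdom))) {
    stop("taxonomy table: kingdom must be non-empty for every genome")
  }
  tab[need]
}

#' Read an aligned FASTA file into a named alignment
#'
#' All rows must have identical gapped length. `.` gap characters are
#' normalized to `-`; residues are uppercased.
#'
#' @param source Path or FASTA text.
#' @return Named character vector of gapped sequences (class
#'   `aa_alignment`), with attribute `n_columns`.
#' @export
read_alignment <- function(source) {
  recs <- parse_fasta(source)
  aln <- gsub(".", "-", recs$sequence, fixed = TRUE)
  names(aln) <- recs$protein_id
  as_alignment(aln)
}

#' Validate a named character vector as an alignment block
#'
#' @param rows Named character vector of gapped sequences.
#' @return The input with class `aa_alignment` and `n_columns` attribute.
#' @export
as_alignment <- function(rows) {
  if (length(rows) == 0L) stop("alignment has no rows")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named")
  }
  if (anyDuplicated(names(rows))) stop("duplicate sequence ids in alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1L) {
    stop("alignment rows have unequal widths: ", paste(w, collapse = ", "))
  }
  structure(toupper(rows), n_columns = w, class = "aa_alignment")
}

#' Parse a Newick tree
#'
#' @param source Newick text or a file path.
#' @return An [ape::phylo] tree. Branch lengths are kept when present.
#' @export
parse_newick <- function(source) {
  txt <- paste(.read_source_lines(source), collapse = "")
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error: malformed tree text")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("Newick validation error: duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("Newick validation error: negative branch length")
  }
  tr
}

#' Serialize a tree to Newick text
#'
#' @param tree An [ape::phylo] tree.
#' @param digits Significant digits for branch lengths.
#' @return Single-element character vector of Newick text.
#' @export
serialize_newick <- function(tree, digits = 10L) {
  ape::write.tree(tree, digits = digits)
}

#' Read and write family profile configurations
#'
#' A profile config is plain text with one clause per line:
#' `family<TAB>acc1|acc2<TAB>min_hits`. Clauses sharing a family name are
#' combined (all must hold).
#'
#' @param source Path or text.
#' @return Named list of [family_profile] objects.
#' @export
read_profiles <- function(source) {
  lines <- .read_source_lines(source)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty profile config")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 3L)
  if (length(bad)) {
    stop("profile config parse error at line ", bad[1L],
         ": expected 3 tab-separated fields")
  }
  fams <- vapply(parts, `[[`, "", 1L)
  profs <- lapply(unique(fams), function(fam) {
    cl <- lapply(parts[fams == fam], function(p) {
      list(alternatives = strsplit(p[2L], "|", fixed = TRUE)[[1L]],
           min_hits = as.integer(p[3L]))
    })
    family_profile(fam, cl)
  })
  names(profs) <- unique(fams)
  profs
}

#' @rdname read_profiles
#' @param profiles Named list of [family_profile] objects.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  lines <- unlist(lapply(profiles, function(p) {
    vapply(p$clauses, function(cl) {
      paste(p$family, paste(cl$alternatives, collapse = "|"), cl$min_hits,
            sep = "\t")
    }, "")
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Write classification calls as TSV
#'
#' Columns: `protein_id`, `genome_id`, `families` (comma-separated, empty
#' when no profile matched) and `evidence` (per-family per-clause matched
#' hit counts).
#'
#' @param calls Calls data frame from [classify_proteome()].
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read classification calls written by [write_calls_tsv()]
#' @param source Path or text.
#' @export
read_calls_tsv <- function(source) {
  lines <- .read_source_lines(source)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "genome_id", "families")
  if (!all(need %in% names(tab))) {
    stop("calls table must have columns: ", paste(need, collapse = ", "))
  }
  tab$families[is.na(tab$families)] <- ""
  tab
}

#' Write and read PHYLIP-style square distance matrices
#'
#' @param d Symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.9f", d[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @param source Path or text of a PHYLIP square matrix.
#' @export
read_phylip_dist <- function(source) {
  lines <- .read_source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) != n + 1L) {
    stop("PHYLIP matrix parse error: bad dimension line or row count")
  }
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
    labs[i] <- f[1L]
    d[i, ] <- as.numeric(f[-1L])
  }
  dimnames(d) <- list(labs, labs)
  d
}
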