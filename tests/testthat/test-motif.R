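aln_basic <- c(
  qde2 = "MADDWHKL",
  s1   = "MADDWHKL",   # identical at anchors
  s2   = "MADDWEKL",   # H -> E
  s3   = "MADDWAKL",   # H -> A
  s4   = "MAADWHKL",   # first D -> A
  s5   = "MADDW-KL")   # gap at third anchor

test_that("reference positions map to alignment columns across gaps", {
  expect_equal(map_reference_columns(c(r = "DDH", x = "DDH"), "r", 1:3),
               1:3)
  expect_equal(map_reference_columns(c(r = "D-DH", x = "DADH"), "r", 1:3),
               c(1L, 3L, 4L))
  expect_error(map_reference_columns(c(r = "D-DH", x = "DADH"), "r", 0L),
               "out of range")
  expect_error(map_reference_columns(c(r = "D-DH", x = "DADH"), "r", 4L),
               "out of range")
  expect_error(map_reference_columns(aln_basic, "nope", 1L), "absent")
})

test_that("looking up mapped columns on the reference returns the requested residues", {
  set.seed(9)
  for (rep in 1:20) {
    ungapped <- paste(sample(LETTERS[1:20], 12, TRUE), collapse = "")
    chars <- strsplit(ungapped, "")[[1]]
    gapped <- character()
    for (ch in chars) {
      gapped <- c(gapped, if (runif(1) < 0.3) "-" else character(), ch)
    }
    row <- paste(gapped, collapse = "")
    other <- paste(rep("A", nchar(row)), collapse = "")
    pos <- sort(sample.int(12, 4))
    cols <- map_reference_columns(c(ref = row, o = other), "ref", pos)
    expect_equal(strsplit(row, "")[[1]][cols], chars[pos])
  }
})

test_that("DDH variant classification follows the category rules", {
  expect_equal(classify_ddh_variant(c("D", "D", "H")), "conserved_DDH")
  for (third in c("D", "E", "K")) {
    expect_equal(classify_ddh_variant(c("D", "D", third)), "H_sub_DEK")
  }
  expect_equal(classify_ddh_variant(c("D", "D", "A")), "H_sub_other")
  expect_equal(classify_ddh_variant(c("A", "D", "H")), "other_variant")
  expect_equal(classify_ddh_variant(c("D", "D", "-")), "missing")
  expect_equal(classify_ddh_variant(c("-", "-", "-")), "missing")
  expect_error(classify_ddh_variant(c("D", "D")), "triple")
})

test_that("the variant classifier is total over every residue triple", {
  letters21 <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  cats <- c("conserved_DDH", "H_sub_DEK", "H_sub_other", "other_variant",
            "missing")
  grid <- expand.grid(a = letters21, b = letters21, c = letters21,
                      stringsAsFactors = FALSE)
  got <- apply(grid, 1L, function(r) classify_ddh_variant(unname(r)))
  expect_true(all(got %in% cats))
  # counts derive from the rule structure: 1 DDH; DD[DEK] = 3;
  # DD + other non-gap third = 20 - 4 = 16; any gap = 21^3 - 20^3
  expect_equal(sum(got == "conserved_DDH"), 1L)
  expect_equal(sum(got == "H_sub_DEK"), 3L)
  expect_equal(sum(got == "H_sub_other"), 16L)
  expect_equal(sum(got == "missing"), 21L^3 - 20L^3)
  expect_equal(sum(got == "other_variant"), 20L^3 - 20L)
})

test_that("motif extraction anchors on the reference and classifies rows", {
  calls <- extract_motif(aln_basic, "qde2", c(3L, 4L, 6L))
  expect_equal(nrow(calls), 5L)
  got <- setNames(calls$category, calls$sequence_id)
  expect_equal(unname(got[c("s1", "s2", "s3", "s4", "s5")]),
               c("conserved_DDH", "H_sub_DEK", "H_sub_other",
                 "other_variant", "missing"))
  expect_equal(calls$residues[calls$sequence_id == "s5"], "DD-")
})

test_that("motif category proportions sum to one per group", {
  calls <- data.frame(
    sequence_id = c("x1", "x2", "x3", "x4", "y1"),
    residues = "DDH",
    category = c("conserved_DDH", "conserved_DDH", "H_sub_DEK",
                 "H_sub_DEK", "other_variant"),
    stringsAsFactors = FALSE)
  seq_genome <- c(x1 = "g1", x2 = "g1", x3 = "g1", x4 = "g1", y1 = "g3")
  tax <- data.frame(genome_id = c("g1", "g3"),
                    kingdom = c("Fungi", "Metazoa"),
                    phylum = "N/D", subphylum = "N/D",
                    stringsAsFactors = FALSE)
  dist <- motif_distribution(calls, seq_genome, tax, level = "kingdom")
  expect_equal(dist$group, c("Fungi", "Metazoa"))
  fungi <- dist[dist$group == "Fungi", ]
  expect_equal(fungi$conserved_DDH, 0.5)
  expect_equal(fungi$H_sub_DEK, 0.5)
  cat_cols <- c("conserved_DDH", "H_sub_DEK", "H_sub_other",
                "other_variant", "missing")
  expect_equal(unname(rowSums(dist[cat_cols])), c(1, 1))
  # single call gives one category at 1.0
  single <- motif_distribution(calls[5, ], seq_genome, tax)
  expect_equal(single$other_variant, 1)
  expect_equal(nrow(single), 1L)
})

test_that("column conservation counts gaps in the denominator and flags at the boundary", {
  aln10 <- setNames(c("D", rep("D", 8), "A"),
                    c("ref", paste0("s", 1:9)))
  prof <- column_conservation(aln10, "ref", 1L)
  expect_equal(prof$fraction, 0.9)
  expect_true(prof$flagged)

  single <- column_conservation(c(only = "DKH"), "only", 1:3)
  expect_equal(single$fraction, c(1, 1, 1))
  expect_true(all(single$flagged))

  # exactly 70% conservation is flagged ("70% or higher")
  aln_boundary <- setNames(c(rep("D", 7), rep("E", 3)),
                           c("ref", paste0("s", 1:9)))
  b <- column_conservation(aln_boundary, "ref", 1L, threshold = 0.70)
  expect_equal(b$fraction, 0.7)
  expect_true(b$flagged)
  just_below <- column_conservation(
    setNames(c(rep("D", 6), rep("E", 4)), c("ref", paste0("s", 1:9))),
    "ref", 1L, threshold = 0.70)
  expect_false(just_below$flagged)

  # gap rows enlarge the denominator without matching
  aln_gap <- c(ref = "D", a = "D", b = "-", c = "-")
  g <- column_conservation(aln_gap, "ref", 1L)
  expect_equal(g$fraction, 0.5)

  expect_error(column_conservation(aln10, "ref", 1L, threshold = 0),
               "threshold")
})

test_that("modal conservation mode scores against the majority residue", {
  aln <- c(ref = "A", a = "E", b = "E", c = "E")
  m <- column_conservation(aln, "ref", 1L, mode = "modal")
  expect_equal(m$fraction, 0.75)
  expect_equal(m$consensus_residue, "E")
  r <- column_conservation(aln, "ref", 1L, mode = "match_reference")
  expect_equal(r$fraction, 0.25)
})

test_that("logo matrices are per-column residue frequencies summing to 1", {
  aln <- c(a = "DD", b = "DD", c = "DE", d = "D-")
  m <- logo_matrix(aln, 1:2)
  expect_equal(m["D", "1"], 1)
  expect_equal(m["D", "2"], 0.5)
  expect_equal(m["E", "2"], 0.25)
  expect_equal(m["-", "2"], 0.25)
  expect_equal(unname(colSums(m)), c(1, 1), tolerance = 1e-12)
  expect_error(logo_matrix(aln, integer()), "empty")
  expect_error(logo_matrix(aln, 3L), "width")
})

test_that("short-domain filtering merges overlapping hits before measuring span", {
  calls <- data.frame(protein_id = c("foxg", "long", "split"),
                      genome_id = "g1", families = "RdRP",
                      stringsAsFactors = FALSE)
  ann <- rbind(
    data.frame(protein_id = "foxg", accession = "IPR007855",
               description = "", start = 100L, end = 167L),   # 68 aa
    data.frame(protein_id = "long", accession = "IPR007855",
               description = "", start = 1L, end = 500L),
    data.frame(protein_id = "split", accession = "IPR007855",
               description = "", start = 1L, end = 60L),
    data.frame(protein_id = "split", accession = "IPR007855",
               description = "", start = 41L, end = 120L))
  kept <- filter_short_domain(calls, ann, "IPR007855",
                              min_domain_span = 100L)
  expect_setequal(kept$protein_id, c("long", "split"))
  expect_error(filter_short_domain(calls, ann, "IPR007855", 0), "positive")
})
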