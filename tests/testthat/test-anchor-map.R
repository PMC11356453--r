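test_that("alignment of identical and near-identical strings scores as BLOSUM62 sums", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b62 <- e$BLOSUM62
  p <- align_global("MKT", "MKT")
  expect_identical(p$ref_aligned, "MKT")
  expect_identical(p$cand_aligned, "MKT")
  expect_equal(p$score, b62["M", "M"] + b62["K", "K"] + b62["T", "T"],
               ignore_attr = TRUE)

  q <- align_global("MKT", "MT")
  expect_identical(q$ref_aligned, "MKT")
  expect_identical(q$cand_aligned, "M-T") # single gap column opposite K
  expect_equal(q$score, b62["M", "M"] + b62["T", "T"] - (10 + 1),
               ignore_attr = TRUE)

  expect_error(align_global("A", ""), "empty")
  expect_error(align_global("AB?", "A"), "unknown character")
})

test_that("alignment scores match an independent DP oracle and Biostrings", {
  sc <- scoring_scheme()
  mat <- sc$substitution_matrix
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- random_protein(sample(5:40, 1))
      b <- random_protein(sample(5:40, 1))
      got <- align_global(a, b, sc)$score
      expect_identical(got, nw_score_oracle(a, b, mat, 10, 1))
      bs <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
      expect_equal(got, Biostrings::score(bs), ignore_attr = TRUE)
    }
  })
})

test_that("alignment pairs ungap back to their inputs and maps are monotone", {
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- random_protein(sample(10:60, 1))
      b <- random_protein(sample(10:60, 1))
      p <- align_global(a, b)
      expect_identical(gsub("-", "", p$ref_aligned), a)
      expect_identical(gsub("-", "", p$cand_aligned), b)
      expect_identical(nchar(p$ref_aligned), nchar(p$cand_aligned))
      expect_false(any(strsplit(p$ref_aligned, "")[[1]] == "-" &
                         strsplit(p$cand_aligned, "")[[1]] == "-"))
      m <- build_position_map(p)
      expect_identical(length(m), nchar(a))
      defined <- m[!is.na(m)]
      expect_true(all(diff(defined) > 0)) # strictly increasing
    }
  })
})

test_that("position maps resolve insertions and deletions as constructed", {
  ident <- build_position_map(list(ref_aligned = "ABCDE", cand_aligned = "ABCDE"))
  expect_identical(ident, 1:5)

  ins <- build_position_map(list(ref_aligned = "AB----CDE",
                                 cand_aligned = "ABWXYZCDE"))
  expect_identical(ins[3], 7L) # 4-residue insertion before reference pos 3

  del <- build_position_map(list(ref_aligned = "ABC", cand_aligned = "A-C"))
  expect_identical(del[2], NA_integer_)
  expect_identical(del[c(1, 3)], c(1L, 2L))
})

test_that("residue_at_anchor returns the reference residue under self-alignment", {
  for (fam in c("DFR", "FLS")) {
    anc <- reference_anchor(fam)
    m <- build_position_map(align_global(anc$reference_protein,
                                         anc$reference_protein))
    r <- residue_at_anchor(anc$reference_protein, m, anc)
    expect_identical(r, substr(anc$reference_protein, anc$anchor_position,
                               anc$anchor_position))
  }
  anc <- reference_anchor("DFR")
  expect_identical(residue_at_anchor("X", rep(NA_integer_,
                                              nchar(anc$reference_protein)), anc),
                   NA_character_)
})

test_that("extract_region returns fixed-width reference-numbered windows", {
  anc <- reference_anchor("DFR")
  m <- build_position_map(align_global(anc$reference_protein,
                                       anc$reference_protein))
  reg <- extract_region(anc$reference_protein, m, 131, 156)
  expect_identical(nchar(reg), 26L)
  expect_identical(reg, substr(anc$reference_protein, 131, 156))

  m2 <- m
  m2[140] <- NA # deletion inside the region
  reg2 <- extract_region(anc$reference_protein, m2, 131, 156)
  expect_identical(nchar(reg2), 26L)
  expect_identical(substr(reg2, 10, 10), "-")

  expect_error(extract_region(anc$reference_protein, m, 140, 135), "start")
})

test_that("planted anchor residues are recovered through alignment", {
  anc <- reference_anchor("DFR")
  cfg <- family_sim_config(family = "DFR", n_sequences = 50,
                           substitution_rate = 0.15, indel_rate = 0.05,
                           planted_anchor_residues = c("N", "D", "A"),
                           seed = 42)
  sim <- simulate_family(cfg)
  rec <- vapply(sim$proteins, function(p) {
    m <- build_position_map(align_global(anc$reference_protein, p))
    r <- residue_at_anchor(p, m, anc)
    if (is.na(r)) "?" else r
  }, character(1))
  expect_identical(unname(rec), sim$truth$planted_residue)
})

test_that("column cleaning applies the strict occupancy boundary and keeps anchors", {
  # 100 rows: column 3 occupancy 0.09 (removed), column 4 occupancy 0.10 (kept)
  base <- "ABCDE"
  rows <- vapply(1:100, function(i) {
    r <- strsplit(base, "")[[1]]
    if (i > 9) r[3] <- "-"
    if (i > 10) r[4] <- "-"
    paste(r, collapse = "")
  }, character(1))
  names(rows) <- paste0("r", 1:100)
  cl <- clean_columns(rows, 0.1)
  expect_identical(cl$kept, c(1L, 2L, 4L, 5L))

  expect_identical(clean_columns(rows[1:5], 0.1)$kept, 1:5) # all ungapped
  expect_identical(clean_columns(rows, 1.0)$kept, c(1L, 2L, 5L))

  # re-anchoring: a surviving anchor column holds the same residue
  anchor_col <- 5L
  new_col <- match(anchor_col, cl$kept)
  expect_identical(substr(cl$msa[["r1"]], new_col, new_col),
                   substr(rows[["r1"]], anchor_col, anchor_col))
})
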