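test_that("anchor classification reproduces the substrate-preference table", {
  n <- classify_anchor("DFR", "N")
  expect_identical(n$type_label, "DFR_N")
  expect_setequal(n$substrates, c("DHK", "DHQ", "DHM"))
  expect_identical(n$confidence, "reported")

  d <- classify_anchor("DFR", "D")
  expect_identical(d$type_label, "DFR_D")
  expect_setequal(d$substrates, c("DHQ", "DHM"))

  a <- classify_anchor("DFR", "A")
  expect_identical(a$type_label, "DFR_A")
  expect_identical(a$substrates, "DHK")

  l <- classify_anchor("DFR", "L") # leucine restricts to DHK but is not a named type
  expect_identical(l$type_label, "DFR_other")
  expect_identical(l$substrates, "DHK")
  expect_identical(l$confidence, "reported")

  h <- classify_anchor("FLS", "H")
  expect_identical(h$type_label, "FLS_H")
  expect_setequal(h$substrates, c("DHK", "DHQ"))
  expect_identical(h$confidence, "hypothesized")
  expect_identical(classify_anchor("FLS", "F")$type_label, "FLS_F")
  expect_identical(classify_anchor("FLS", "F")$substrates, "DHK")
  expect_identical(classify_anchor("FLS", "Y")$type_label, "FLS_Y")
  expect_identical(classify_anchor("FLS", "Y")$substrates, "DHQ")

  v <- classify_anchor("FLS", "V") # fall-through
  expect_identical(v$type_label, "FLS_other")
  expect_length(v$substrates, 0)
  expect_identical(v$confidence, "none")

  expect_error(classify_anchor("ANS", "Y"), "unknown family")
})

test_that("anchor classification is total over residues and handles deletions", {
  residues <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y", NA)
  for (fam in c("FLS", "DFR")) {
    for (r in residues) {
      out <- classify_anchor(fam, r)
      expect_true(is.character(out$type_label) && nzchar(out$type_label))
      if (is.na(r)) expect_identical(out$type_label, "absent")
    }
  }
})

test_that("residue rules pass on the reference and fail on planted violations", {
  anc <- reference_anchor("FLS")
  rules <- default_rules("FLS")
  m <- build_position_map(align_global(anc$reference_protein,
                                       anc$reference_protein))
  self <- screen_rules(anc$reference_protein, m, rules)
  expect_true(self$functional)
  expect_identical(nrow(self$failed), 0L)

  # G68 -> D violates the 2-ODD fold rule
  mutated <- anc$reference_protein
  substr(mutated, 68, 68) <- "D"
  scr <- screen_rules(mutated, m, rules)
  expect_false(scr$functional)
  expect_true(68L %in% scr$failed$ref_position)
  expect_identical(scr$failed$observed[scr$failed$ref_position == 68L], "D")

  # deletion at a rule position reports ABSENT
  m2 <- m; m2[75] <- NA
  scr2 <- screen_rules(anc$reference_protein, m2, rules)
  expect_false(scr2$functional)
  expect_identical(scr2$failed$observed[scr2$failed$ref_position == 75L], "ABSENT")
})

test_that("motif scanning matches a naive oracle on planted and random sequences", {
  expect_identical(find_motif("AAPQRSIRTUVEQPZZ", "PxxxIRxxxEQP"), 3L)
  expect_identical(find_motif("HADQQQQH", "Hx[DE]x{1,10}H"), 1L)
  expect_identical(find_motif("AAAA", "PxxxIRxxxEQP"), integer(0))
  expect_error(find_motif("AAAA", "P"), "too short")

  withr::with_seed(77, {
    for (i in 1:100) {
      s <- random_protein(200)
      if (i %% 3 == 0) { # plant matches in a third of the cases
        pos <- sample(1:160, 1)
        substr(s, pos, pos + 11) <- "PABCIRDEFEQP"
      }
      expect_identical(find_motif(s, "PxxxIRxxxEQP"),
                       naive_scan_fixed(s, "PxxxIRxxxEQP"))
      expect_identical(find_motif(s, "SxxTxLVP"),
                       naive_scan_fixed(s, "SxxTxLVP"))
      expect_identical(find_motif(s, "Hx[DE]x{40,150}H"),
                       naive_scan_fe(s, 40, 150))
    }
  })
})

test_that("type_sequences recovers planted types and flags broken sequences", {
  anc <- reference_anchor("DFR")
  cfg <- family_sim_config(family = "DFR", n_sequences = 60,
                           substitution_rate = 0.1, indel_rate = 0.02,
                           planted_anchor_residues = c("N", "D", "A"), seed = 5)
  sim <- simulate_family(cfg)
  ty <- type_sequences(sim$cds, anc)
  expect_identical(nrow(ty), 60L)
  expect_identical(ty$type_label, sim$truth$planted_type)
  expect_identical(ty$anchor_residue, sim$truth$planted_residue)

  # deterministic given config
  ty2 <- type_sequences(sim$cds, anc)
  expect_identical(ty, ty2)

  # internal stop is flagged and kills the functional flag
  cds_stop <- sim$cds[1]
  s <- cds_stop[[1]]
  substr(s, 301, 303) <- "TGA" # in-frame internal stop (codon 101)
  cds_stop[[1]] <- s
  tys <- type_sequences(structure(cds_stop, molecule = "cds"), anc)
  expect_true(tys$internal_stop[1])
  expect_false(tys$functional[1])
  expect_match(tys$failed_checks[1], "internal_stop")

  expect_identical(nrow(type_sequences(character(0), anc)), 0L)
})

test_that("typing separates functional FLS from rule-violating FLS-like sequences", {
  anc <- reference_anchor("FLS")
  good <- anc$reference_protein
  bad <- good
  substr(bad, 202, 202) <- "A" # K202 violation
  ty <- type_sequences(c(fn = good, like = bad), anc)
  expect_true(ty$functional[ty$seq_id == "fn"])
  expect_false(ty$functional[ty$seq_id == "like"])
  expect_match(ty$failed_checks[ty$seq_id == "like"], "pos202=A")
  expect_identical(ty$type_label, c("FLS_H", "FLS_H")) # typing is screen-independent
})

test_that("per-group summaries report modal residues and patterns", {
  res <- data.frame(
    seq_id = paste0("s", 1:6),
    family = "FLS",
    anchor_residue = c("F", "F", "F", "Y", "H", "H"),
    type_label = c("FLS_F", "FLS_F", "FLS_F", "FLS_Y", "FLS_H", "FLS_H"),
    substrates = "", confidence = "", functional = TRUE,
    failed_checks = "", internal_stop = FALSE, stringsAsFactors = FALSE)
  grouping <- c(s1 = "Poales", s2 = "Poales", s3 = "Poales", s4 = "Poales",
                s5 = "Rosales", s6 = "Rosales")
  sm <- summarize_types(res, grouping)
  expect_identical(sm$modal_residue[sm$group == "Poales"], "F")
  expect_identical(sm$pattern[sm$group == "Poales"], "F/Y")
  expect_identical(sm$n, c(4L, 2L))

  # empty group level is omitted with a warning
  grouping2 <- c(grouping, s99 = "Fabales")
  expect_warning(sm2 <- summarize_types(res, grouping2), "Fabales")
  expect_false("Fabales" %in% sm2$group)

  # invariance under input permutation
  perm <- sample(nrow(res))
  sm3 <- summarize_types(res[perm, ], grouping)
  expect_identical(sm, sm3)
})
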