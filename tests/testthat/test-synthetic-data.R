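test_that("zero-rate family simulation returns reference-identical homologs", {
  anc <- reference_anchor("DFR")
  ref_residue <- substr(anc$reference_protein, 133, 133)
  cfg <- family_sim_config(family = "DFR", n_sequences = 5,
                           substitution_rate = 0, indel_rate = 0,
                           planted_anchor_residues = ref_residue, seed = 8)
  sim <- simulate_family(cfg)
  expect_true(all(sim$proteins == anc$reference_protein))
  expect_true(all(sim$truth$anchor_pos == 133L))
  expect_true(all(vapply(seq_len(5), function(i) {
    as.character(translate_cds(sim$cds[[i]])) == sim$proteins[[i]]
  }, logical(1))))
})

test_that("simulators are pure functions of config and seed", {
  cfg <- family_sim_config(family = "FLS", n_sequences = 10,
                           planted_anchor_residues = c("H", "F", "Y"), seed = 12)
  s1 <- simulate_family(cfg)
  s2 <- simulate_family(cfg)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(s1$cds, f1)
  write_fasta(s2$cds, f2)
  expect_identical(readLines(f1), readLines(f2))

  e1 <- simulate_expression(expr_sim_config(n_species = 2,
                                            samples_per_species = 3, seed = 4))
  e2 <- simulate_expression(expr_sim_config(n_species = 2,
                                            samples_per_species = 3, seed = 4))
  expect_identical(e1$abundance, e2$abundance)
  expect_error(expr_sim_config(n_species = 2), "seed")
  expect_error(family_sim_config(family = "DFR"), "seed")
})

test_that("planted anchor codons are recorded faithfully in the truth table", {
  cfg <- family_sim_config(family = "DFR", n_sequences = 30,
                           substitution_rate = 0.05, indel_rate = 0.02,
                           planted_anchor_residues = c("N", "A"), seed = 19)
  sim <- simulate_family(cfg)
  for (i in seq_len(30)) {
    tru <- sim$truth[i, ]
    expect_identical(codon_at(sim$cds[[i]], tru$anchor_pos), tru$anchor_codon)
    expect_identical(unname(Biostrings::GENETIC_CODE[tru$anchor_codon]),
                     tru$planted_residue)
  }
})

test_that("rho extremes behave exactly as constructed", {
  e1 <- simulate_expression(expr_sim_config(n_species = 3,
                                            samples_per_species = 10,
                                            rho = 1, noise_floor = 0,
                                            seed = 21))
  expect_true(all(pmin(e1$truth$samples$fls_tpm, e1$truth$samples$dfr_tpm) == 0))

  e0 <- simulate_expression(expr_sim_config(n_species = 3,
                                            samples_per_species = 10,
                                            rho = 0, noise_floor = 0.01,
                                            seed = 22))
  expect_true(all(e0$truth$samples$expressed == "both"))
})

test_that("Dirichlet paralog splits aggregate back to the family totals", {
  sim <- simulate_expression(expr_sim_config(n_species = 2,
                                             samples_per_species = 5,
                                             rho = 0.5, paralogs_per_family = 3,
                                             seed = 23))
  tab <- merge_samples(sim$abundance, sim$meta)
  gty <- sim_gene_typing(sim)
  agg <- aggregate_paralogs(tab, gty, sim$proteins, identity_threshold = 0.8)
  pairs <- pair_focal(agg, gty)
  m <- merge(pairs, sim$truth$samples, by = "sample_id")
  expect_equal(m$fls_tpm.x, m$fls_tpm.y, tolerance = 1e-9)
  expect_equal(m$dfr_tpm.x, m$dfr_tpm.y, tolerance = 1e-9)
})

test_that("generated files are consumed by the standard readers unchanged", {
  dir <- withr::local_tempdir()
  sim <- simulate_expression(expr_sim_config(n_species = 2,
                                             samples_per_species = 2, seed = 6))
  write_expression_sim(sim, dir)
  ab_files <- list.files(dir, pattern = "_abundance\\.tsv$", full.names = TRUE)
  expect_identical(length(ab_files), 4L)
  back <- read_abundance_tsv(ab_files[1])
  expect_identical(colnames(back),
                   c("target_id", "length", "eff_length", "est_counts", "tpm"))
  prot <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_identical(attr(prot, "molecule"), "protein")

  fam <- simulate_family(family_sim_config(family = "DFR", n_sequences = 3,
                                           seed = 2))
  ff <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam$cds, ff)
  expect_identical(unname(read_fasta(ff)[names(fam$cds)]), unname(c(fam$cds)))
})

test_that("recovery scoring reports accuracies and rejects empty truth", {
  anc <- reference_anchor("DFR")
  cfg <- family_sim_config(family = "DFR", n_sequences = 20,
                           substitution_rate = 0, indel_rate = 0, seed = 31)
  sim <- simulate_family(cfg)
  ty <- type_sequences(sim$cds, anc)
  sc <- score_recovery(typing = ty, family_truth = sim$truth)
  expect_identical(sc$anchor_accuracy, 1)
  expect_identical(sc$type_accuracy, 1)

  ty_bad <- ty
  ty_bad$type_label[1] <- "DFR_other"
  ty_bad$anchor_residue[1] <- "W"
  sc2 <- score_recovery(typing = ty_bad, family_truth = sim$truth)
  expect_equal(sc2$type_accuracy, 19 / 20)

  expect_error(score_recovery(typing = ty, family_truth = sim$truth[0, ]),
               "non-empty truth")
  expect_error(score_recovery(), "nothing to score")
})
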