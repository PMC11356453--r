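make_tables <- function(samples, genes, tpm_fun) {
  tabs <- lapply(samples, function(s) {
    data.frame(target_id = genes, length = 900, eff_length = 750,
               est_counts = tpm_fun(s) * 2, tpm = tpm_fun(s),
               stringsAsFactors = FALSE)
  })
  names(tabs) <- samples
  tabs
}

test_that("sample merging builds genes x samples matrices with validation", {
  genes <- paste0("g", 1:5)
  tabs <- make_tables(c("s1", "s2", "s3"), genes, function(s) 1:5)
  meta <- data.frame(sample_id = c("s1", "s2", "s3"), species = "sp1",
                     organ = "leaf")
  tab <- merge_samples(tabs, meta)
  expect_identical(dim(tab$tpm), c(5L, 3L))
  expect_identical(colnames(tab$tpm), c("s1", "s2", "s3"))

  tabs2 <- tabs
  tabs2$s2$target_id[5] <- "gX"
  expect_error(merge_samples(tabs2, meta), "gX|g5")
  expect_error(merge_samples(list(), meta), "no samples")
  expect_error(merge_samples(tabs[1:2], meta), "without data")
  expect_error(merge_samples(tabs, meta[1:2, ]), "missing from metadata")
})

test_that("paralog aggregation merges same-residue close paralogs only", {
  ref <- toy_reference("FLS")
  p_h1 <- ref
  p_h2 <- ref; substr(p_h2, 10, 10) <- "A" # ~0.997 identity to p_h1
  p_y <- ref; substr(p_y, 132, 132) <- "Y"
  prot <- c(fls_h1 = p_h1, fls_h2 = p_h2, fls_y = p_y)

  genes <- names(prot)
  tabs <- make_tables(c("s1", "s2"), genes,
                      function(s) if (s == "s1") c(10, 5, 2) else c(1, 2, 3))
  meta <- data.frame(sample_id = c("s1", "s2"), species = "sp1", organ = "leaf")
  tab <- merge_samples(tabs, meta)
  typing <- data.frame(seq_id = genes, family = "FLS",
                       anchor_residue = c("H", "H", "Y"),
                       type_label = c("FLS_H", "FLS_H", "FLS_Y"),
                       substrates = "", confidence = "", functional = TRUE,
                       failed_checks = "", internal_stop = FALSE,
                       stringsAsFactors = FALSE)

  agg <- aggregate_paralogs(tab, typing, prot, identity_threshold = 0.95)
  expect_true("fls_h1+fls_h2" %in% rownames(agg$tpm))
  expect_identical(unname(agg$tpm["fls_h1+fls_h2", "s1"]), 15)
  expect_true("fls_y" %in% rownames(agg$tpm)) # different residue: never merged
  # per-sample totals conserved
  expect_equal(colSums(agg$tpm), colSums(tab$tpm), tolerance = 1e-12)

  none <- aggregate_paralogs(tab, typing, prot, identity_threshold = 1.01)
  expect_identical(sort(rownames(none$tpm)), sort(rownames(tab$tpm)))
})

test_that("per-sample pairing sums functional focal genes and tags types", {
  sim <- simulate_expression(expr_sim_config(n_species = 2,
                                             samples_per_species = 4,
                                             rho = 1, noise_floor = 0.01,
                                             seed = 3))
  tab <- merge_samples(sim$abundance, sim$meta)
  gty <- sim_gene_typing(sim)
  pairs <- pair_focal(tab, gty)
  expect_identical(nrow(pairs), 8L)
  expect_true(all(c("fls_tpm", "dfr_tpm", "fls_type", "dfr_type") %in%
                    colnames(pairs)))
  combo <- sim$truth$species
  for (i in seq_len(nrow(combo))) {
    sub <- pairs[pairs$species == combo$species[i], ]
    expect_true(all(sub$fls_type == combo$fls_type[i]))
    expect_true(all(sub$dfr_type == combo$dfr_type[i]))
  }

  # a species without functional DFR is excluded with a warning
  gty2 <- gty
  gty2$functional[gty2$family == "DFR" & gty2$seq_id ==
                    grep("^species01_DFR", gty2$seq_id, value = TRUE)[1]] <- FALSE
  expect_warning(p2 <- pair_focal(tab, gty2), "excluded")
  expect_false("species01" %in% p2$species)

  # absent combination: empty result, not an error
  p3 <- pair_focal(tab, gty, combination = c("FLS_F", "DFR_D"))
  expect_identical(nrow(p3), 0L)
})

test_that("exclusivity index hits its closed-form extremes and invariances", {
  ones <- data.frame(fls_tpm = c(10, 0, 3), dfr_tpm = c(0, 7, 0))
  expect_identical(exclusivity_index(ones, 1)$index, 1)

  zeros <- data.frame(fls_tpm = c(5, 2), dfr_tpm = c(5, 2))
  expect_identical(exclusivity_index(zeros, 1)$index, 0)

  expect_error(exclusivity_index(data.frame(fls_tpm = 0.1, dfr_tpm = 0.2), 1),
               "no sample")

  withr::with_seed(41, {
    p <- data.frame(fls_tpm = rlnorm(100, 2, 1), dfr_tpm = rlnorm(100, 2, 1))
    i0 <- exclusivity_index(p, 1)$index
    swapped <- data.frame(fls_tpm = p$dfr_tpm, dfr_tpm = p$fls_tpm)
    expect_equal(exclusivity_index(swapped, 1)$index, i0)
    scaled <- p * 7.3
    expect_equal(exclusivity_index(scaled, 7.3)$index, i0)
  })
})

test_that("density grids conserve counts and transpose under axis swap", {
  withr::with_seed(43, {
    p <- data.frame(fls_tpm = rlnorm(100, 3, 1), dfr_tpm = rlnorm(100, 1, 1))
    g <- density_grid(p, bins = 20)
    expect_identical(sum(g$grid), 100L)
    expect_identical(g$fls_marginal, rowSums(g$grid))
    expect_identical(g$dfr_marginal, colSums(g$grid))

    swapped <- data.frame(fls_tpm = p$dfr_tpm, dfr_tpm = p$fls_tpm)
    g2 <- density_grid(swapped, bins = 20)
    expect_identical(g2$grid, t(g$grid))

    same <- data.frame(fls_tpm = rep(5, 30), dfr_tpm = rep(2, 30))
    gs <- density_grid(same, bins = 20)
    expect_identical(sum(gs$grid > 0), 1L)
    expect_identical(max(gs$grid), 30L)
  })
})
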