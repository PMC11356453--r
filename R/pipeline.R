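# High-level pipeline runners: each wraps one stage end-to-end with file
# input/output, so the command-line script stays a thin argument parser.
# All randomness flows from the single `seed` argument; rerunning with the
# same inputs and seed reproduces the outputs byte for byte (modulo
# timestamps in the run log).

log_msg <- function(log_con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(log_con)) writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                           msg), log_con)
}

open_run_log <- function(out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "run_log.txt"), "w")
  writeLines(c("# flavotype run log",
               paste0("# ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               "# config:",
               paste0("#   ", names(config), " = ",
                      vapply(config, function(x) paste(format(x), collapse = ","),
                             character(1)))), con)
  con
}

#' Run the typing stage on a FASTA file
#'
#' Reads sequences (CDS or protein), types them against the family
#' reference and writes `typing.tsv` plus, when a grouping is supplied,
#' `type_summary.tsv`.
#'
#' @param fasta Path to input FASTA.
#' @param out_dir Output directory.
#' @param family `"FLS"` or `"DFR"`.
#' @param anchor Optional [reference_anchor()] override.
#' @param rules_file,motifs_file Optional TSV overrides for the shipped
#'   rule/motif configuration.
#' @param grouping Optional named character vector (seq id -> group) for
#'   [summarize_types()].
#' @return The `typing_result`, invisibly; files under `out_dir`.
#' @export
run_type <- function(fasta, out_dir, family = c("FLS", "DFR"), anchor = NULL,
                     rules_file = NULL, motifs_file = NULL, grouping = NULL) {
  family <- match.arg(family)
  if (is.null(anchor)) anchor <- reference_anchor(family)
  rules <- if (is.null(rules_file)) default_rules(family) else {
    if (!file.exists(rules_file)) stop("rule file not found: ", rules_file)
    read.delim(rules_file, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
  }
  motifs <- if (is.null(motifs_file)) default_motifs(family) else {
    if (!file.exists(motifs_file)) stop("motif file not found: ", motifs_file)
    read.delim(motifs_file, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
  }
  con <- open_run_log(out_dir, list(stage = "type", fasta = fasta, family = family))
  on.exit(close(con))
  records <- read_fasta(fasta)
  typing <- type_sequences(records, anchor, rules = rules, motifs = motifs)
  write_typing_tsv(typing, file.path(out_dir, "typing.tsv"))
  log_msg(con, "typed ", nrow(typing), " sequences: ",
          sum(typing$functional), " functional, ",
          sum(!typing$functional & typing$type_label != "absent"), " -like, ",
          sum(typing$type_label == "absent"), " anchor-absent")
  if (!is.null(grouping)) {
    write.table(summarize_types(typing, grouping),
                file.path(out_dir, "type_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(typing)
}

#' Run the tree stage on a protein FASTA
#'
#' Aligns every sequence to the family reference (pairwise, reference
#' columns only) to obtain comparable rows, builds the NJ tree with
#' bootstrap support, annotates leaves with typing results when available,
#' and writes `tree.nwk` plus `itol_colorstrip.txt`.
#'
#' @param fasta Protein or CDS FASTA.
#' @param out_dir Output directory.
#' @param family `"FLS"` or `"DFR"`.
#' @param typing_tsv Optional path to a `typing.tsv` from [run_type()].
#' @param bootstrap_reps Bootstrap replicates (default 100).
#' @param seed Integer seed for the bootstrap.
#' @return List with `tree`, `support`, invisibly.
#' @export
run_tree <- function(fasta, out_dir, family = c("FLS", "DFR"),
                     typing_tsv = NULL, bootstrap_reps = 100L, seed = 1L) {
  family <- match.arg(family)
  anchor <- reference_anchor(family)
  con <- open_run_log(out_dir, list(stage = "tree", fasta = fasta,
                                    family = family, seed = seed,
                                    bootstrap_reps = bootstrap_reps))
  on.exit(close(con))
  records <- read_fasta(fasta)
  prot <- if (attr(records, "molecule") == "cds") translate_set(records)$proteins
          else records
  # project every candidate onto reference columns for a common coordinate frame
  msa <- vapply(prot, function(p) {
    pr <- gsub("*", "X", p, fixed = TRUE)
    map <- build_position_map(align_global(anchor$reference_protein, pr))
    extract_region(pr, map, 1L, nchar(anchor$reference_protein))
  }, character(1))
  bs <- bootstrap_support(msa, n_reps = bootstrap_reps, seed = seed)
  log_msg(con, "NJ tree over ", length(msa), " sequences, ",
          bootstrap_reps, " bootstrap replicates")
  if (!is.null(typing_tsv)) {
    if (!file.exists(typing_tsv)) stop("typing TSV not found: ", typing_tsv)
    typing <- read_typing_tsv(typing_tsv)
    ann <- annotate_tree(bs$tree, typing)
    write_newick(ann$tree, file.path(out_dir, "tree_annotated.nwk"))
    write_itol_strip(ann, file.path(out_dir, "itol_colorstrip.txt"))
  }
  write_newick(bs$tree, file.path(out_dir, "tree.nwk"))
  write.table(bs$support, file.path(out_dir, "bootstrap_support.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bs)
}

#' Run the expression stage on a directory of abundance tables
#'
#' Consumes kallisto-dialect `*_abundance.tsv` files plus `samples.tsv`
#' metadata, a typing TSV and a protein FASTA (for paralog identity),
#' applies the paralog-sum rule, pairs FLS/DFR per sample, and writes
#' `pairs.tsv`, `exclusivity.json` and `density_grid.tsv`.
#'
#' @param data_dir Directory with `*_abundance.tsv` and `samples.tsv` (as
#'   written by [write_expression_sim()]).
#' @param out_dir Output directory.
#' @param typing_tsv Path to a typing TSV (required).
#' @param proteins_fasta Path to the focal-gene protein FASTA (required for
#'   paralog aggregation; skip aggregation if `NULL`).
#' @param identity_threshold Paralog identity threshold (default 0.8).
#' @param min_total_tpm Detection floor for the exclusivity index.
#' @param bins Density-grid bins per axis.
#' @return List with `pairs`, `exclusivity`, `grid`, invisibly.
#' @export
run_expression <- function(data_dir, out_dir, typing_tsv,
                           proteins_fasta = NULL, identity_threshold = 0.8,
                           min_total_tpm = 1, bins = 50L) {
  if (is.null(typing_tsv) || !file.exists(typing_tsv)) {
    stop("run_expression requires the typing TSV produced by run_type(); ",
         "not found: ", typing_tsv %||% "<missing>")
  }
  meta_file <- file.path(data_dir, "samples.tsv")
  if (!file.exists(meta_file)) stop("sample metadata not found: ", meta_file)
  con <- open_run_log(out_dir, list(stage = "expression", data_dir = data_dir,
                                    identity_threshold = identity_threshold,
                                    min_total_tpm = min_total_tpm, bins = bins))
  on.exit(close(con))
  typing <- read_typing_tsv(typing_tsv)
  meta <- read.delim(meta_file, sep = "\t", stringsAsFactors = FALSE)
  files <- list.files(data_dir, pattern = "_abundance\\.tsv$", full.names = TRUE)
  tables <- lapply(files, read_abundance_tsv)
  names(tables) <- sub("_abundance\\.tsv$", "", basename(files))
  tab <- merge_samples(tables, meta)
  if (!is.null(proteins_fasta)) {
    prot <- read_fasta(proteins_fasta, molecule = "protein")
    tab <- aggregate_paralogs(tab, typing, prot, identity_threshold)
  }
  pairs <- pair_focal(tab, typing)
  excl <- exclusivity_index(pairs, min_total_tpm)
  grid <- density_grid(pairs, bins)
  write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(index = excl$index, n_used = excl$n_used,
                            min_total_tpm = min_total_tpm,
                            identity_threshold = identity_threshold,
                            note = paste("exclusivity index = median |F-D|/(F+D)",
                                         "over samples with F+D >= min_total_tpm;",
                                         "statistic defined by this package")),
                       file.path(out_dir, "exclusivity.json"),
                       auto_unbox = TRUE, digits = NA)
  write_grid_tsv(grid, file.path(out_dir, "density_grid.tsv"))
  log_msg(con, "paired ", nrow(pairs), " samples; exclusivity index = ",
          signif(excl$index, 4), " (n = ", excl$n_used, ")")
  invisible(list(pairs = pairs, exclusivity = excl, grid = grid))
}

#' Run the simulation stage
#'
#' Writes a synthetic family (CDS + protein FASTA + truth table) and a
#' synthetic expression dataset under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param family `"FLS"` or `"DFR"` for the sequence family.
#' @param n_sequences,substitution_rate,indel_rate Family simulator knobs.
#' @param planted_anchor_residues Residues planted at the anchor.
#' @param n_species,samples_per_species,rho Expression simulator knobs.
#' @param seed Integer seed driving both generators.
#' @return List with `family`, `expression` simulation objects, invisibly.
#' @export
run_simulate <- function(out_dir, family = c("DFR", "FLS"), n_sequences = 200L,
                         substitution_rate = 0.1, indel_rate = 0.02,
                         planted_anchor_residues = NULL,
                         n_species = 5L, samples_per_species = 20L, rho = 0.9,
                         seed = 1L) {
  family <- match.arg(family)
  if (is.null(planted_anchor_residues)) {
    planted_anchor_residues <- if (family == "DFR") c("N", "D", "A")
                               else c("H", "F", "Y")
  }
  con <- open_run_log(out_dir, list(stage = "simulate", family = family,
                                    n_sequences = n_sequences, seed = seed,
                                    substitution_rate = substitution_rate,
                                    indel_rate = indel_rate, rho = rho))
  on.exit(close(con))
  fam <- simulate_family(family_sim_config(
    family = family, n_sequences = n_sequences,
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    planted_anchor_residues = planted_anchor_residues, seed = seed))
  write_fasta(fam$cds, file.path(out_dir, "family_cds.fasta"))
  write_fasta(fam$proteins, file.path(out_dir, "family_proteins.fasta"))
  write.table(fam$truth, file.path(out_dir, "family_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expr <- simulate_expression(expr_sim_config(
    n_species = n_species, samples_per_species = samples_per_species,
    rho = rho, seed = seed + 1L))
  write_expression_sim(expr, file.path(out_dir, "expression"))
  # a typing table for the simulated genes, so run_expression() can run
  # directly on the synthetic dataset
  gtyping <- data.frame(seq_id = expr$genes$gene_id, family = expr$genes$family,
                        anchor_residue = expr$genes$anchor_residue,
                        type_label = expr$genes$type_label,
                        substrates = "", confidence = "",
                        functional = expr$genes$functional,
                        failed_checks = "", internal_stop = FALSE,
                        stringsAsFactors = FALSE)
  write_typing_tsv(gtyping, file.path(out_dir, "expression", "genes_typing.tsv"))
  log_msg(con, "simulated ", n_sequences, " ", family, " homologs and ",
          n_species * samples_per_species, " expression samples (rho = ", rho, ")")
  invisible(list(family = fam, expression = expr))
}
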