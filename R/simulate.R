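# Ground-truth simulators for sequence families and expression tables.
#
# Both generators are pure functions of (config, seed): running the same
# configuration twice yields byte-identical output. They emulate, at desk
# scale, the two data shapes the pipeline consumes: CDS families diverged
# from a reference by substitutions and indels with a planted residue at
# the anchor column, and per-sample kallisto-style abundance tables where
# one of the two focal genes is expressed per sample with tunable
# exclusivity.

# codon -> aa and aa -> codons under the standard code (stops excluded)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

random_codon_for <- function(aa, inv) {
  cods <- inv[[aa]]
  cods[sample.int(length(cods), 1L)]
}

#' Configuration for the sequence-family simulator
#'
#' @param reference_protein Reference protein string (default: the packaged
#'   synthetic toy reference for `family`).
#' @param anchor_position 1-based anchor position (defaults to the family
#'   anchor: DFR 133, FLS 132).
#' @param family `"FLS"` or `"DFR"`.
#' @param n_sequences Number of homologs to generate.
#' @param substitution_rate Per-site substitution probability in \[0, 1).
#' @param indel_rate Per-site indel initiation probability in \[0, 1).
#' @param indel_p Geometric length parameter: indel length ~ 1 + Geom(p).
#' @param planted_anchor_residues Residues sampled (uniformly, or with
#'   `planted_weights`) for the anchor column.
#' @param planted_weights Optional sampling weights.
#' @param protect_anchor If `TRUE` (default) no indel overlaps the anchor
#'   column.
#' @param seed Mandatory integer seed.
#' @return A `family_sim_config` list.
#' @export
family_sim_config <- function(reference_protein = NULL, anchor_position = NULL,
                              family = c("DFR", "FLS"), n_sequences = 200L,
                              substitution_rate = 0.1, indel_rate = 0.02,
                              indel_p = 0.5,
                              planted_anchor_residues = c("N", "D", "A"),
                              planted_weights = NULL, protect_anchor = TRUE,
                              seed) {
  family <- match.arg(family)
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(reference_protein)) reference_protein <- toy_reference(family)
  anchor_position <- as.integer(anchor_position %||%
                                  if (family == "DFR") 133L else 132L)
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            indel_p > 0, indel_p <= 1,
            anchor_position >= 1L, anchor_position <= nchar(reference_protein),
            all(planted_anchor_residues %in% AA20))
  structure(list(reference_protein = reference_protein,
                 anchor_position = anchor_position, family = family,
                 n_sequences = as.integer(n_sequences),
                 substitution_rate = substitution_rate, indel_rate = indel_rate,
                 indel_p = indel_p,
                 planted_anchor_residues = planted_anchor_residues,
                 planted_weights = planted_weights,
                 protect_anchor = isTRUE(protect_anchor),
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

#' Simulate a diverged sequence family with planted anchor residues
#'
#' Each homolog derives from the reference by iid substitutions and
#' geometric-length indels; the anchor column carries a residue drawn from
#' `planted_anchor_residues`, back-translated to a uniformly chosen
#' synonymous codon (recorded in the truth table). Indels never start in
#' the first or last three columns. When `protect_anchor` is set, no indel
#' touches a three-column guard window around the anchor: since the planted
#' residue generally differs from the reference residue, an indel directly
#' flanking the anchor would make the anchor column irrecoverable in
#' principle (no aligner could tell which residue of an inserted run is the
#' anchor), so the guard is what keeps the planted ground truth
#' well-defined.
#'
#' @param cfg A [family_sim_config()].
#' @return List with `cds` (named character vector), `proteins`, and
#'   `truth`: data frame `seq_id`, `planted_residue`, `anchor_codon`,
#'   `anchor_pos` (1-based position in the mutated protein; `NA` when an
#'   unprotected indel deleted the anchor), `planted_type`.
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "family_sim_config"))
  inv <- codon_table()
  ref <- chars(cfg$reference_protein)
  n_ref <- length(ref)
  a <- cfg$anchor_position
  with_seed(cfg$seed, {
    cds <- character(cfg$n_sequences)
    prot <- character(cfg$n_sequences)
    truth <- vector("list", cfg$n_sequences)
    for (s in seq_len(cfg$n_sequences)) {
      planted <- if (is.null(cfg$planted_weights)) {
        sample(cfg$planted_anchor_residues, 1L)
      } else {
        sample(cfg$planted_anchor_residues, 1L, prob = cfg$planted_weights)
      }
      aa <- ref
      # iid substitutions (anchor column is set afterwards)
      hit <- which(runif(n_ref) < cfg$substitution_rate)
      for (p in hit) aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
      aa[a] <- planted
      anchor_idx <- a

      # indels: initiation sites away from the first/last 3 columns
      sites <- which(runif(n_ref) < cfg$indel_rate)
      sites <- sites[sites > 3L & sites <= n_ref - 3L]
      # apply from the right so earlier site coordinates stay valid
      for (p in rev(sites)) {
        len <- 1L + rgeom(1L, cfg$indel_p)
        if (runif(1) < 0.5) { # deletion of aa[p .. p+len-1]
          q <- min(p + len - 1L, length(aa))
          if (cfg$protect_anchor && !is.na(anchor_idx) &&
              p <= anchor_idx + 3L && q >= anchor_idx - 3L) next
          if (!is.na(anchor_idx)) {
            if (q < anchor_idx) anchor_idx <- anchor_idx - (q - p + 1L)
            else if (p <= anchor_idx) anchor_idx <- NA_integer_
          }
          aa <- aa[-(p:q)]
        } else {             # insertion after position p
          if (cfg$protect_anchor && !is.na(anchor_idx) &&
              p >= anchor_idx - 3L && p <= anchor_idx + 2L) next
          ins <- sample(AA20, len, replace = TRUE)
          aa <- append(aa, ins, after = p)
          if (!is.na(anchor_idx) && p < anchor_idx) anchor_idx <- anchor_idx + len
        }
      }

      # back-translate with uniform synonymous codons, then a stop codon
      codons <- vapply(aa, random_codon_for, character(1), inv = inv)
      anchor_codon <- if (!is.na(anchor_idx)) codons[[anchor_idx]] else NA_character_
      stop_codon <- sample(inv[["*"]], 1L)
      cds[s] <- paste(c(codons, stop_codon), collapse = "")
      prot[s] <- paste(aa, collapse = "")
      truth[[s]] <- data.frame(
        seq_id = sprintf("%s_sim_%03d", cfg$family, s),
        planted_residue = planted, anchor_codon = anchor_codon,
        anchor_pos = anchor_idx,
        planted_type = classify_anchor(cfg$family, planted)$type_label,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    names(cds) <- truth$seq_id
    names(prot) <- truth$seq_id
    list(cds = structure(cds, molecule = "cds"),
         proteins = structure(prot, molecule = "protein"),
         truth = truth)
  })
}

#' Configuration for the expression simulator
#'
#' @param n_species Number of species.
#' @param samples_per_species Samples per species.
#' @param rho Exclusivity in \[0, 1\]: probability that exactly one of
#'   FLS/DFR is expressed in a sample (the other sits at the noise floor);
#'   with probability `1 - rho` both are expressed.
#' @param mu,sigma Lognormal (meanlog, sdlog) of the "on" TPM.
#' @param noise_floor "Off" genes draw TPM ~ Uniform(0, `noise_floor`).
#'   Must be below `exp(mu)`.
#' @param paralogs_per_family Number of same-type paralogs the on-gene's
#'   TPM is split over (Dirichlet split), per family.
#' @param paralog_identity Target protein identity of simulated paralog
#'   sequences to their family toy reference (substitutions only).
#' @param organs Organ labels cycled over samples.
#' @param seed Mandatory integer seed.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_species = 5L, samples_per_species = 20L,
                            rho = 0.9, mu = log(100), sigma = 1,
                            noise_floor = 0.01, paralogs_per_family = 1L,
                            paralog_identity = 0.95,
                            organs = c("leaf", "root", "stem", "flower",
                                       "seed", "fruit"),
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(rho >= 0, rho <= 1, noise_floor < exp(mu), noise_floor >= 0,
            n_species >= 1, samples_per_species >= 1, paralogs_per_family >= 1)
  structure(list(n_species = as.integer(n_species),
                 samples_per_species = as.integer(samples_per_species),
                 rho = rho, mu = mu, sigma = sigma, noise_floor = noise_floor,
                 paralogs_per_family = as.integer(paralogs_per_family),
                 paralog_identity = paralog_identity, organs = organs,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

# A paralog protein: the family toy reference with the planted anchor
# residue and random substitutions down to ~identity.
paralog_protein <- function(family, anchor_residue, identity) {
  ref <- chars(toy_reference(family))
  a <- if (family == "DFR") 133L else 132L
  n_sub <- round((1 - identity) * length(ref))
  pos <- sample(setdiff(seq_along(ref), a), n_sub)
  for (p in pos) ref[p] <- sample(setdiff(AA20, ref[p]), 1L)
  ref[a] <- anchor_residue
  paste(ref, collapse = "")
}

#' Simulate per-sample abundance tables with tunable FLS/DFR exclusivity
#'
#' Every species gets one FLS type and one DFR type (cycled over the
#' reported combinations) with `paralogs_per_family` paralog genes each,
#' plus two background genes. Per sample, with probability `rho` exactly
#' one of FLS/DFR is on (TPM ~ lognormal; the other at the noise floor),
#' otherwise both are on; the on-family TPM is split over its paralogs by
#' a symmetric Dirichlet draw.
#'
#' @param cfg An [expr_sim_config()].
#' @return List with `abundance` (named list of kallisto-dialect data
#'   frames, one per sample), `meta` (sample metadata), `genes` (per-gene
#'   annotation: species, family, anchor_residue, type_label, functional),
#'   `proteins` (named character), and `truth` (per-sample expressed gene
#'   call, per-sample family TPM totals, per-species type combination).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  combos <- list(c("H", "N"), c("F", "N"), c("Y", "N"), c("H", "D"), c("H", "A"))
  with_seed(cfg$seed, {
    abundance <- list()
    meta <- list()
    genes <- list()
    proteins <- character(0)
    truth_samples <- list()
    truth_species <- list()
    for (sp_i in seq_len(cfg$n_species)) {
      sp <- sprintf("species%02d", sp_i)
      combo <- combos[[(sp_i - 1L) %% length(combos) + 1L]]
      fls_res <- combo[1]; dfr_res <- combo[2]
      fls_ids <- sprintf("%s_FLS_%d", sp, seq_len(cfg$paralogs_per_family))
      dfr_ids <- sprintf("%s_DFR_%d", sp, seq_len(cfg$paralogs_per_family))
      bg_ids <- paste0(sp, c("_bg_1", "_bg_2"))
      for (id in fls_ids) proteins[[id]] <- paralog_protein("FLS", fls_res,
                                                           cfg$paralog_identity)
      for (id in dfr_ids) proteins[[id]] <- paralog_protein("DFR", dfr_res,
                                                           cfg$paralog_identity)
      genes[[sp]] <- data.frame(
        gene_id = c(fls_ids, dfr_ids, bg_ids), species = sp,
        family = c(rep("FLS", length(fls_ids)), rep("DFR", length(dfr_ids)),
                   rep("other", 2L)),
        anchor_residue = c(rep(fls_res, length(fls_ids)),
                           rep(dfr_res, length(dfr_ids)), NA, NA),
        type_label = c(rep(classify_anchor("FLS", fls_res)$type_label, length(fls_ids)),
                       rep(classify_anchor("DFR", dfr_res)$type_label, length(dfr_ids)),
                       NA, NA),
        functional = c(rep(TRUE, length(fls_ids) + length(dfr_ids)), FALSE, FALSE),
        stringsAsFactors = FALSE)
      truth_species[[sp]] <- data.frame(
        species = sp,
        fls_type = classify_anchor("FLS", fls_res)$type_label,
        dfr_type = classify_anchor("DFR", dfr_res)$type_label,
        stringsAsFactors = FALSE)

      gene_ids <- genes[[sp]]$gene_id
      glen <- setNames(rep(c(900L, 720L, 600L), c(length(fls_ids),
                                                  length(dfr_ids), 2L)), gene_ids)
      for (k in seq_len(cfg$samples_per_species)) {
        sid <- sprintf("%s_s%02d", sp, k)
        organ <- cfg$organs[(k - 1L) %% length(cfg$organs) + 1L]
        exclusive <- runif(1) < cfg$rho
        on_family <- if (exclusive) sample(c("FLS", "DFR"), 1L) else "both"
        fam_tpm <- c(FLS = 0, DFR = 0)
        for (fam in c("FLS", "DFR")) {
          fam_tpm[[fam]] <- if (on_family %in% c(fam, "both")) {
            rlnorm(1L, cfg$mu, cfg$sigma)
          } else {
            runif(1L, 0, cfg$noise_floor)
          }
        }
        split_tpm <- function(total, k_genes) {
          if (k_genes == 1L) return(total)
          w <- rgamma(k_genes, shape = 1)
          total * w / sum(w)
        }
        tpm <- setNames(numeric(length(gene_ids)), gene_ids)
        tpm[fls_ids] <- split_tpm(fam_tpm[["FLS"]], length(fls_ids))
        tpm[dfr_ids] <- split_tpm(fam_tpm[["DFR"]], length(dfr_ids))
        tpm[bg_ids] <- rlnorm(2L, cfg$mu / 2, cfg$sigma)
        counts <- round(tpm * glen / 1000, 3)
        abundance[[sid]] <- data.frame(
          target_id = gene_ids, length = unname(glen),
          eff_length = unname(glen) - 150, est_counts = unname(counts),
          tpm = unname(tpm), stringsAsFactors = FALSE)
        meta[[sid]] <- data.frame(sample_id = sid, species = sp, organ = organ,
                                  stringsAsFactors = FALSE)
        truth_samples[[sid]] <- data.frame(
          sample_id = sid, species = sp, expressed = on_family,
          fls_tpm = unname(fam_tpm[["FLS"]]), dfr_tpm = unname(fam_tpm[["DFR"]]),
          stringsAsFactors = FALSE)
      }
    }
    list(abundance = abundance,
         meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         genes = do.call(rbind, c(unname(genes), list(make.row.names = FALSE))),
         proteins = proteins,
         truth = list(samples = do.call(rbind, c(truth_samples,
                                                 list(make.row.names = FALSE))),
                      species = do.call(rbind, c(unname(truth_species),
                                                 list(make.row.names = FALSE)))))
  })
}

#' Write a simulated expression dataset to disk
#'
#' Writes one kallisto-dialect `*_abundance.tsv` per sample plus
#' `samples.tsv` metadata, `genes.tsv` annotation and `proteins.fasta`.
#'
#' @param sim Result of [simulate_expression()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_expression_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(sim$abundance)) {
    write_abundance_tsv(sim$abundance[[sid]],
                        file.path(dir, paste0(sid, "_abundance.tsv")))
  }
  write.table(sim$meta, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  invisible(dir)
}

#' Score pipeline outputs against a simulation truth table
#'
#' Compares what the pipeline recovered with what the generator planted:
#' anchor residues and type labels against a [simulate_family()] truth
#' table, and/or expressed-gene calls against a [simulate_expression()]
#' truth table (a sample is called `FLS`/`DFR` when only that family
#' exceeds the floor, `both` otherwise).
#'
#' @param typing Optional `typing_result` to score against `truth$truth`
#'   of a family simulation (data frame with `seq_id`, `planted_residue`,
#'   `planted_type`).
#' @param family_truth Optional family-simulation truth table.
#' @param pairs Optional [pair_focal()] output to score.
#' @param expression_truth Optional expression-simulation per-sample truth.
#' @param call_floor TPM floor for the expressed-gene call (default 1).
#' @return List of per-stage accuracies and confusion tables.
#' @export
score_recovery <- function(typing = NULL, family_truth = NULL, pairs = NULL,
                           expression_truth = NULL, call_floor = 1) {
  out <- list()
  if (!is.null(typing) || !is.null(family_truth)) {
    if (is.null(typing) || is.null(family_truth) || nrow(family_truth) == 0L) {
      stop("scoring sequence typing needs both typing results and a non-empty truth table")
    }
    m <- merge(family_truth, as.data.frame(typing), by = "seq_id")
    obs_res <- ifelse(is.na(m$anchor_residue), "ABSENT", m$anchor_residue)
    exp_res <- ifelse(is.na(m$anchor_pos), "ABSENT", m$planted_residue)
    exp_type <- ifelse(is.na(m$anchor_pos), "absent", m$planted_type)
    out$anchor_accuracy <- mean(obs_res == exp_res)
    out$type_accuracy <- mean(m$type_label == exp_type)
    out$anchor_confusion <- table(planted = exp_res, observed = obs_res)
    out$type_confusion <- table(planted = exp_type, observed = m$type_label)
  }
  if (!is.null(pairs) || !is.null(expression_truth)) {
    if (is.null(pairs) || is.null(expression_truth) || nrow(expression_truth) == 0L) {
      stop("scoring expression calls needs both pairs and a non-empty truth table")
    }
    call_of <- function(f, d) {
      if (f >= call_floor && d < call_floor) "FLS"
      else if (d >= call_floor && f < call_floor) "DFR"
      else "both"
    }
    m <- merge(expression_truth, pairs, by = "sample_id",
               suffixes = c(".truth", ""))
    obs <- mapply(call_of, m$fls_tpm, m$dfr_tpm)
    exp_call <- mapply(call_of, m$fls_tpm.truth, m$dfr_tpm.truth)
    out$expression_call_accuracy <- mean(obs == exp_call)
    out$expression_confusion <- table(truth = exp_call, observed = obs)
  }
  if (length(out) == 0L) stop("nothing to score")
  out
}
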