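# Cross-sample expression merging and FLS-vs-DFR exclusivity statistics.
#
# All pairing and index computations run on TPM (length- and
# depth-normalized); est_counts are carried along and summed by the same
# paralog-aggregation rule.

#' Merge per-sample abundance tables into an expression table
#'
#' Samples are merged into genes x samples TPM and count matrices. Within a
#' species every sample must quantify the identical gene universe; genes of
#' one species are `NA` in samples of another.
#'
#' @param tables Named list of data frames as returned by
#'   [read_abundance_tsv()]; names are sample ids.
#' @param meta Data frame with columns `sample_id`, `species`, `organ`.
#'   Must cover exactly the samples in `tables`.
#' @return An `expr_table`: list with `tpm`, `counts` (matrices, genes x
#'   samples, columns ordered by sample id), `meta`, and `gene_species`
#'   (named character).
#' @export
merge_samples <- function(tables, meta) {
  if (length(tables) == 0L) stop("no samples to merge")
  stopifnot(!is.null(names(tables)),
            all(c("sample_id", "species", "organ") %in% colnames(meta)))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  extra <- setdiff(names(tables), meta$sample_id)
  if (length(extra)) stop("sample(s) missing from metadata: ",
                          paste(extra, collapse = ", "))
  absent <- setdiff(meta$sample_id, names(tables))
  if (length(absent)) stop("metadata sample(s) without data: ",
                           paste(absent, collapse = ", "))
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  sp_of_sample <- setNames(meta$species, meta$sample_id)
  gene_species <- character(0)
  for (sp in unique(meta$species)) {
    ids <- meta$sample_id[meta$species == sp]
    universe <- sort(tables[[ids[1]]]$target_id)
    for (sid in ids) {
      got <- sort(tables[[sid]]$target_id)
      if (!identical(got, universe)) {
        diffg <- c(setdiff(universe, got), setdiff(got, universe))
        stop("gene universe mismatch within species ", sp, " (sample ", sid,
             "): ", paste(diffg, collapse = ", "))
      }
    }
    gene_species[universe] <- sp
  }
  genes <- names(gene_species)
  tpm <- matrix(NA_real_, length(genes), nrow(meta),
                dimnames = list(genes, meta$sample_id))
  counts <- tpm
  for (sid in meta$sample_id) {
    tb <- tables[[sid]]
    tpm[tb$target_id, sid] <- tb$tpm
    counts[tb$target_id, sid] <- tb$est_counts
  }
  structure(list(tpm = tpm, counts = counts, meta = meta,
                 gene_species = gene_species),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat("expr_table: ", nrow(x$tpm), " genes x ", ncol(x$tpm), " samples (",
      length(unique(x$meta$species)), " species)\n", sep = "")
  invisible(x)
}

# Pairwise protein identity = matching columns / alignment length.
protein_identity <- function(a, b, scoring = scoring_scheme()) {
  pair <- align_global(a, b, scoring)
  ra <- chars(pair$ref_aligned); ca <- chars(pair$cand_aligned)
  mean(ra == ca)
}

#' Sum close same-type paralogs into single rows
#'
#' Within one species and family, genes that share the same anchor residue
#' and are mutually similar (pairwise protein identity >= threshold,
#' single-linkage) are replaced by one row holding their TPM and count
#' sums. Genes with different anchor residues are never merged, so
#' per-sample totals over focal genes are conserved exactly.
#'
#' @param table An `expr_table`.
#' @param typing A `typing_result` covering the focal genes (`seq_id`
#'   matching rownames of the matrices).
#' @param proteins Named character vector of protein sequences for the
#'   focal genes (needed for the identity computation).
#' @param identity_threshold Fraction in (0, 1\]; values above 1 disable
#'   merging. Default 0.8.
#' @return A new `expr_table`; merged rows are named by joining member ids
#'   with `+`, and a `paralog_groups` attribute records the grouping.
#' @export
aggregate_paralogs <- function(table, typing, proteins, identity_threshold = 0.8) {
  stopifnot(inherits(table, "expr_table"))
  focal <- intersect(typing$seq_id, rownames(table$tpm))
  groups <- list()
  info <- typing[match(focal, typing$seq_id), , drop = FALSE]
  info$species <- table$gene_species[focal]
  keyed <- split(focal, paste(info$species, info$family, info$anchor_residue,
                              sep = "\r"))
  for (ids in keyed) {
    if (length(ids) < 2L || anyNA(proteins[ids])) {
      groups <- c(groups, as.list(ids)); next
    }
    # single-linkage components under the identity threshold
    k <- length(ids)
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (protein_identity(proteins[[ids[i]]], proteins[[ids[j]]]) >= identity_threshold) {
        parent[find(j)] <- find(i)
      }
    }
    comp <- vapply(seq_len(k), find, integer(1))
    groups <- c(groups, unname(split(ids, comp)))
  }
  nonfocal <- setdiff(rownames(table$tpm), focal)
  groups <- c(groups, as.list(nonfocal))

  sum_rows <- function(mat) {
    out <- do.call(rbind, lapply(groups, function(ids) {
      colSums(mat[ids, , drop = FALSE])
    }))
    rownames(out) <- vapply(groups, paste, character(1), collapse = "+")
    out
  }
  new_species <- vapply(groups, function(ids) table$gene_species[[ids[1]]], character(1))
  names(new_species) <- vapply(groups, paste, character(1), collapse = "+")
  out <- structure(list(tpm = sum_rows(table$tpm), counts = sum_rows(table$counts),
                        meta = table$meta, gene_species = new_species),
                   class = "expr_table")
  attr(out, "paralog_groups") <- groups
  attr(out, "identity_threshold") <- identity_threshold
  out
}

# Map (possibly merged "a+b") rownames back to typing rows.
row_typing <- function(rown, typing) {
  first <- vapply(strsplit(rown, "+", fixed = TRUE), `[`, character(1), 1L)
  typing[match(first, typing$seq_id), , drop = FALSE]
}

#' Per-sample (FLS, DFR) expression pairs
#'
#' For each sample, sums the TPM of all functional FLS rows and all
#' functional DFR rows belonging to the sample's species, tagged with the
#' type combination. Samples of species lacking a functional member of
#' either family are excluded with a warning. A requested type combination
#' absent from the data yields an empty result, not an error.
#'
#' @param table An `expr_table` (typically after [aggregate_paralogs()]).
#' @param typing A `typing_result` covering the focal genes. For merged
#'   rows the first member id is looked up.
#' @param combination Optional `c(fls_type, dfr_type)` restriction, e.g.
#'   `c("FLS_H", "DFR_N")`.
#' @return Data frame `sample_id`, `species`, `organ`, `fls_tpm`,
#'   `dfr_tpm`, `fls_type`, `dfr_type`.
#' @export
pair_focal <- function(table, typing, combination = NULL) {
  stopifnot(inherits(table, "expr_table"))
  ti <- row_typing(rownames(table$tpm), typing)
  ti$row <- rownames(table$tpm)
  ti <- ti[!is.na(ti$seq_id) & ti$functional, , drop = FALSE]
  ti$species <- table$gene_species[ti$row]
  if (!is.null(combination)) {
    stopifnot(length(combination) == 2L)
    ti <- ti[(ti$family == "FLS" & ti$type_label == combination[1]) |
             (ti$family == "DFR" & ti$type_label == combination[2]), , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(table$meta)), function(i) {
    sid <- table$meta$sample_id[i]
    sp <- table$meta$species[i]
    fls <- ti[ti$species == sp & ti$family == "FLS", , drop = FALSE]
    dfr <- ti[ti$species == sp & ti$family == "DFR", , drop = FALSE]
    if (nrow(fls) == 0L || nrow(dfr) == 0L) return(NULL)
    data.frame(sample_id = sid, species = sp, organ = table$meta$organ[i],
               fls_tpm = sum(table$tpm[fls$row, sid]),
               dfr_tpm = sum(table$tpm[dfr$row, sid]),
               fls_type = paste(sort(unique(fls$type_label)), collapse = "+"),
               dfr_type = paste(sort(unique(dfr$type_label)), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0L && is.null(combination)) {
    warning(skipped, " sample(s) excluded: species lacks a functional FLS or DFR")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), species = character(0),
                      organ = character(0), fls_tpm = numeric(0),
                      dfr_tpm = numeric(0), fls_type = character(0),
                      dfr_type = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Mutual-exclusivity index of paired expression
#'
#' Over samples whose total focal expression passes the detection floor
#' (`fls_tpm + dfr_tpm >= min_total_tpm`), the index is the median of
#' `|F - D| / (F + D)`: 1 means perfectly exclusive expression (only one
#' gene on per sample), 0 perfectly balanced co-expression. This index is a
#' statistic defined by this package to quantify the qualitative
#' either-FLS-or-DFR expression pattern; it is invariant under swapping the
#' two genes and under rescaling all TPM by a positive constant.
#'
#' @param pairs Data frame with columns `fls_tpm`, `dfr_tpm` (see
#'   [pair_focal()]).
#' @param min_total_tpm Detection floor, > 0 (default 1).
#' @return List with `index`, `n_used`, `ratios` (per retained sample).
#' @export
exclusivity_index <- function(pairs, min_total_tpm = 1) {
  stopifnot(min_total_tpm > 0,
            all(c("fls_tpm", "dfr_tpm") %in% colnames(pairs)))
  tot <- pairs$fls_tpm + pairs$dfr_tpm
  keep <- tot >= min_total_tpm
  if (!any(keep)) stop("no sample passes the min_total_tpm filter")
  r <- abs(pairs$fls_tpm[keep] - pairs$dfr_tpm[keep]) / tot[keep]
  list(index = median(r), n_used = sum(keep), ratios = r)
}

#' 2D expression density grid with marginal histograms
#'
#' Bins the per-sample (FLS, DFR) TPM pairs on log10(TPM + 1) axes into a
#' `bins` x `bins` count grid (FLS on rows, DFR on columns) with shared
#' axis breaks, so swapping the two genes transposes the grid. Marginals
#' are the row and column sums. Rendering (see [plot_exclusivity()]) uses a
#' log color scale with pseudocount 1.
#'
#' @param pairs Data frame with `fls_tpm`, `dfr_tpm`.
#' @param bins Number of bins per axis (default 50).
#' @return List of class `density_grid`: `grid`, `breaks`,
#'   `fls_marginal`, `dfr_marginal`, `n`.
#' @export
density_grid <- function(pairs, bins = 50L) {
  bins <- as.integer(bins)
  stopifnot(bins >= 1L, nrow(pairs) > 0L)
  f <- log10(pairs$fls_tpm + 1)
  d <- log10(pairs$dfr_tpm + 1)
  hi <- max(f, d)
  if (hi == 0) hi <- 1
  breaks <- seq(0, hi, length.out = bins + 1L)
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), bins)
  grid <- matrix(0L, bins, bins)
  fi <- bin_of(f); di <- bin_of(d)
  for (k in seq_along(fi)) grid[fi[k], di[k]] <- grid[fi[k], di[k]] + 1L
  list(grid = grid, breaks = breaks,
       fls_marginal = rowSums(grid), dfr_marginal = colSums(grid),
       n = nrow(pairs)) |>
    structure(class = "density_grid")
}

#' Write a density grid as TSV
#' @param g A `density_grid`.
#' @param path Output path.
#' @export
write_grid_tsv <- function(g, path) {
  write.table(g$grid, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Heatmap of FLS vs DFR expression with marginal histograms
#'
#' Requires ggplot2 (and patchwork for the assembled marginal layout).
#' Color is log10(count + 1).
#'
#' @param pairs Data frame with `fls_tpm`, `dfr_tpm`.
#' @param bins Bins per axis.
#' @return A ggplot / patchwork object.
#' @export
plot_exclusivity <- function(pairs, bins = 50L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_exclusivity requires ggplot2")
  }
  g <- density_grid(pairs, bins)
  mids <- (g$breaks[-1] + g$breaks[-length(g$breaks)]) / 2
  df <- expand.grid(fls = mids, dfr = mids)
  df$count <- as.vector(g$grid)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fls, y = .data$dfr,
                                        fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(count + 1)") +
    ggplot2::labs(x = "log10(FLS TPM + 1)", y = "log10(DFR TPM + 1)") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    mf <- data.frame(x = mids, n = g$fls_marginal)
    md <- data.frame(x = mids, n = g$dfr_marginal)
    top <- ggplot2::ggplot(mf, ggplot2::aes(.data$x, .data$n)) +
      ggplot2::geom_col(width = diff(g$breaks)[1]) +
      ggplot2::labs(x = NULL, y = "samples") + ggplot2::theme_minimal()
    right <- ggplot2::ggplot(md, ggplot2::aes(.data$x, .data$n)) +
      ggplot2::geom_col(width = diff(g$breaks)[1]) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "samples") + ggplot2::theme_minimal()
    p <- top + patchwork::plot_spacer() + p + right +
      patchwork::plot_layout(ncol = 2, widths = c(4, 1), heights = c(1, 4))
  }
  p
}
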