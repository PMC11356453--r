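# Neighbor-joining phylogenetics with bootstrap support and type-annotated
# tree export.
#
# Distances are protein p-distances (pairwise deletion by default); trees
# are ape "phylo" objects throughout, so externally computed newick trees
# can be dropped in at any point.

#' Protein p-distance matrix
#'
#' `d[i,j]` = mismatches / compared columns. Under pairwise deletion a
#' column is compared for a pair iff neither row has a gap there; otherwise
#' (complete deletion) columns containing any gap are removed first.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param pairwise_deletion Logical, default `TRUE`.
#' @return Symmetric numeric matrix with zero diagonal and sequence names
#'   as dimnames.
#' @export
pdistance <- function(msa, pairwise_deletion = TRUE) {
  stopifnot(length(msa) >= 2L, !is.null(names(msa)))
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  if (!pairwise_deletion) {
    m <- m[, colSums(m == "-") == 0L, drop = FALSE]
    if (ncol(m) == 0L) stop("no comparable columns after complete deletion")
  }
  n <- length(msa)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      nc <- sum(ok)
      if (nc == 0L) stop("no comparable columns between ", names(msa)[i],
                         " and ", names(msa)[j])
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix. Ties in the Q criterion
#' are broken by the smallest (i, j) index pair in the current matrix
#' ordering (joined nodes are appended last), so the result is fully
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sister edge. Exactly reconstructs additive
#' distances.
#'
#' @param d Symmetric distance matrix with labelled dimnames (at least 3).
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  stopifnot(max(abs(d - t(d))) < 1e-12, all(diag(d) == 0))

  sub <- as.list(labels)           # newick fragments per active node
  D <- d
  fmt <- function(x) sprintf("%.17g", x)
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minimal Q (tolerant comparison)
    qmin <- min(Q)
    best <- NULL
    for (i in seq_len(r - 1L)) {
      jhit <- which(Q[i, (i + 1L):r] <= qmin + 1e-12)
      if (length(jhit)) { best <- c(i, i + jhit[1]); break }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    ll <- clamp2(li, lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newd <- newd[-c(i, j)]
    merged <- paste0("(", sub[[i]], ":", fmt(ll[1]), ",", sub[[j]], ":", fmt(ll[2]), ")")
    sub <- c(sub[-c(i, j)], merged)
    D <- rbind(cbind(D[-c(i, j), -c(i, j), drop = FALSE], newd),
               c(newd, 0))
    dimnames(D) <- NULL
  }
  # resolve the final three nodes around a central vertex
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  txt <- paste0("(", sub[[1]], ":", fmt(l1), ",", sub[[2]], ":", fmt(l2), ",",
                sub[[3]], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

# Canonical bipartition keys (leaf sets not containing the first label,
# sorted and comma-joined); trivial splits excluded.
tree_splits <- function(tree, all_labels) {
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  ref <- sort(all_labels)[1]
  keys <- vapply(pp, function(idx) {
    side <- tips[idx]
    if (ref %in% side) side <- setdiff(all_labels, side)
    if (length(side) < 2L || length(side) > length(all_labels) - 2L) return(NA_character_)
    paste(sort(side), collapse = ",")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the full-data NJ
#' tree the percentage of replicates containing it. Deterministic given
#' `seed`.
#'
#' @param msa Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param pairwise_deletion Passed to [pdistance()].
#' @return List with `tree` (the full-data NJ `phylo`, with `node.label`
#'   carrying support where defined) and `support` (data frame `split`,
#'   `support` in \[0, 100\]).
#' @export
bootstrap_support <- function(msa, n_reps, seed, pairwise_deletion = TRUE) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be a positive integer")
  tree <- neighbor_joining(pdistance(msa, pairwise_deletion))
  labels <- names(msa)
  target <- tree_splits(tree, labels)
  counts <- setNames(numeric(length(target)), target)
  L <- unique(nchar(msa))
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- setNames(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""),
                          labels)
      rep_tree <- neighbor_joining(pdistance(rep_msa, pairwise_deletion))
      hit <- tree_splits(rep_tree, labels)
      hit <- intersect(hit, target)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- data.frame(split = target, support = 100 * counts / n_reps,
                        stringsAsFactors = FALSE, row.names = NULL)
  # attach support as internal node labels where a node realizes a split
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  ref <- sort(labels)[1]
  node_label <- vapply(seq_along(pp), function(k) {
    side <- tips[pp[[k]]]
    if (ref %in% side) side <- setdiff(labels, side)
    key <- paste(sort(side), collapse = ",")
    if (key %in% names(counts)) sprintf("%g", 100 * counts[[key]] / n_reps) else ""
  }, character(1))
  tree$node.label <- node_label
  list(tree = tree, support = support)
}

#' Substrate-type colors for tree annotation
#'
#' Injective color map over the nine type labels plus `"untyped"`.
#' @return Named character vector of hex colors.
#' @export
type_colors <- function() {
  c(DFR_N = "#b6a6e3", DFR_D = "#8c9fe8", DFR_A = "#5b2d8f",
    DFR_other = "#9e9e9e",
    FLS_H = "#f5e6a3", FLS_F = "#e07b00", FLS_Y = "#b8860b",
    FLS_other = "#7f7f7f",
    absent = "#4d4d4d", untyped = "#d9d9d9")
}

#' Annotate tree leaves with typing results
#'
#' Topology and branch lengths are never altered: the returned tree only
#' has its tip labels extended to `id|type_label`. Leaves without a typing
#' result are labelled `untyped`; results for unknown leaves are dropped
#' with a warning.
#'
#' @param tree A `phylo` tree.
#' @param typing A `typing_result` data frame.
#' @return List with `tree` (relabelled copy), `annotations` (data frame
#'   `leaf`, `type_label`, `color`) and `itol` (character vector: an
#'   iTOL COLORSTRIP dataset, one line per element).
#' @export
annotate_tree <- function(tree, typing) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(typing$seq_id, tree$tip.label)
  if (length(unknown)) {
    warning("typing results for leaves not in tree, ignored: ",
            paste(unknown, collapse = ", "))
  }
  types <- setNames(typing$type_label, typing$seq_id)
  lab <- ifelse(tree$tip.label %in% names(types),
                unname(types[tree$tip.label]), "untyped")
  cols <- type_colors()
  ann <- data.frame(leaf = tree$tip.label, type_label = lab,
                    color = unname(cols[lab]), stringsAsFactors = FALSE)
  out <- tree
  out$tip.label <- paste0(tree$tip.label, "|", lab)
  itol <- c("DATASET_COLORSTRIP", "SEPARATOR TAB",
            "DATASET_LABEL\tsubstrate-preference type", "COLOR\t#888888",
            "DATA",
            paste(ann$leaf, ann$color, ann$type_label, sep = "\t"))
  list(tree = out, annotations = ann, itol = itol)
}

#' @rdname annotate_tree
#' @param annotation Result of `annotate_tree()`.
#' @param path Output path for the iTOL color-strip file.
#' @export
write_itol_strip <- function(annotation, path) {
  writeLines(annotation$itol, path)
  invisible(path)
}

#' Per-clade type composition and monophyly verdicts
#'
#' For every internal node, counts the type labels of the leaves below it.
#' A type is monophyletic iff some node's subtree contains exactly the
#' leaves of that type; single-leaf types are monophyletic by definition.
#'
#' @param tree A `phylo` tree.
#' @param annotations Data frame `leaf`, `type_label` (as from
#'   [annotate_tree()]).
#' @return List with `clades` (long data frame `node`, `type_label`, `count`)
#'   and `monophyly` (data frame `type_label`, `n_leaves`, `monophyletic`).
#' @export
clade_type_summary <- function(tree, annotations) {
  stopifnot(inherits(tree, "phylo"))
  types <- setNames(annotations$type_label, annotations$leaf)
  leaf_type <- types[tree$tip.label]
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  ntip <- length(tips)
  clades <- do.call(rbind, lapply(seq_along(pp), function(k) {
    below <- tips[pp[[k]]]
    tc <- table(types[below], useNA = "no")
    if (length(tc) == 0L) return(NULL)
    data.frame(node = ntip + k, type_label = names(tc),
               count = as.integer(tc), stringsAsFactors = FALSE)
  }))
  rownames(clades) <- NULL
  subtree_sets <- c(as.list(tips), lapply(pp, function(idx) tips[idx]))
  mono <- do.call(rbind, lapply(unique(leaf_type[!is.na(leaf_type)]), function(tl) {
    members <- sort(tree$tip.label[!is.na(leaf_type) & leaf_type == tl])
    hit <- any(vapply(subtree_sets,
                      function(s) identical(sort(s), members), logical(1)))
    data.frame(type_label = tl, n_leaves = length(members), monophyletic = hit,
               stringsAsFactors = FALSE)
  }))
  rownames(mono) <- NULL
  list(clades = clades, monophyly = mono)
}

#' Write a distance matrix as PHYLIP-style square TSV
#'
#' @param d Labelled symmetric matrix.
#' @param path Output path.
#' @export
write_distance_tsv <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], sprintf("%.10g", d[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}
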