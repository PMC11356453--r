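# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results through different code paths.

# Score-only affine-gap DP (Durbin-style three-state), independent of the
# package's C++ traceback implementation.
nw_score_oracle <- function(a, b, mat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Y[i + 1, 1] <- -(gap_open + gap_extend * i)
  for (j in seq_len(m)) X[1, j + 1] <- -(gap_open + gap_extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- prev + mat[A[i], B[j]]
      Y[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             Y[i, j + 1] - gap_extend,
                             X[i, j + 1] - gap_open - gap_extend)
      X[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             X[i + 1, j] - gap_extend,
                             Y[i + 1, j] - gap_open - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Naive position-by-position scans for the motif shapes under test.
naive_scan_fixed <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(pc)
  hits <- integer(0)
  if (length(sc) < L) return(hits)
  for (s in seq_len(length(sc) - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (pc[k] != "x" && sc[s + k - 1L] != pc[k]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# H - any - (D|E) - n wildcards (nmin..nmax) - H
naive_scan_fe <- function(seq, nmin, nmax) {
  sc <- strsplit(seq, "")[[1]]
  N <- length(sc)
  hits <- integer(0)
  for (s in seq_len(N)) {
    if (sc[s] != "H" || s + 3L + nmin > N) next
    if (!(sc[s + 2L] %in% c("D", "E"))) next
    ends <- (s + 3L + nmin):min(s + 3L + nmax, N)
    if (any(sc[ends] == "H")) hits <- c(hits, s)
  }
  hits
}

# Quartet oracle: among the three pairings of four taxa, additive distances
# satisfy the four-point condition for the true split.
quartet_split_oracle <- function(d) {
  stopifnot(nrow(d) == 4L)
  l <- rownames(d)
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  pairing <- list(c(l[1], l[2]), c(l[1], l[3]), c(l[1], l[4]))
  pairing[[which.min(sums)]]
}

# Random protein of length n over the 20 standard residues.
random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

# Random CDS of n_codons sense codons (no stops).
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Random additive distance matrix from a random topology with edges in
# [0.1, 1]; returns the generating tree and its path-distance matrix.
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Gene-annotation table of a simulated expression dataset in typing_result
# shape, so expression functions can consume simulator ground truth.
sim_gene_typing <- function(sim) {
  out <- data.frame(seq_id = sim$genes$gene_id, family = sim$genes$family,
                    anchor_residue = sim$genes$anchor_residue,
                    type_label = sim$genes$type_label,
                    substrates = "", confidence = "",
                    functional = sim$genes$functional,
                    failed_checks = "", internal_stop = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("typing_result", "data.frame")
  out
}

# Two 5-taxon blocks separated by n_diagnostic diagnostic columns, plus
# per-taxon noise columns so within-group taxa are distinguishable.
make_block_msa <- function(n_diagnostic = 50) {
  withr::with_seed(101, {
    taxa <- c(paste0("g1_", 1:5), paste0("g2_", 1:5))
    diag_cols <- rbind(matrix("A", 5, n_diagnostic), matrix("T", 5, n_diagnostic))
    noise <- matrix(sample(c("G", "C", "S", "R", "K", "L", "M", "N", "P", "Q"),
                           10 * 40, replace = TRUE), nrow = 10)
    m <- cbind(diag_cols, noise)
    stats::setNames(apply(m, 1, paste, collapse = ""), taxa)
  })
}
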