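# Reference-anchored position mapping.
#
# Candidate proteins are globally aligned to a family reference with an
# affine-gap Needleman-Wunsch (BLOSUM62 by default); reference-numbered
# positions -- in particular the substrate-preference anchors, DFR 133 and
# FLS 132 in Arabidopsis numbering -- are then mapped through the gap
# structure onto candidate coordinates.

blosum62_env <- new.env(parent = emptyenv())

# BLOSUM62 over the 20 standard residues plus X; X scores 0 against
# everything (neutral ambiguity).
default_substitution_matrix <- function() {
  if (is.null(blosum62_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b <- e$BLOSUM62[AA20, AA20]
    m <- matrix(0, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
    m[AA20, AA20] <- b
    blosum62_env$mat <- m
  }
  blosum62_env$mat
}

#' Alignment scoring scheme
#'
#' @param substitution_matrix Symmetric integer substitution matrix with
#'   residue dimnames. Default: BLOSUM62 extended with an `X` row/column
#'   scoring 0 against everything.
#' @param gap_open Gap opening penalty (positive). A gap run of length L
#'   costs `gap_open + L * gap_extend`.
#' @param gap_extend Gap extension penalty (positive).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(substitution_matrix = NULL, gap_open = 10,
                           gap_extend = 1) {
  if (is.null(substitution_matrix)) substitution_matrix <- default_substitution_matrix()
  stopifnot(is.matrix(substitution_matrix),
            identical(rownames(substitution_matrix), colnames(substitution_matrix)),
            isTRUE(all.equal(substitution_matrix, t(substitution_matrix))),
            gap_open > 0, gap_extend > 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal global alignment of two proteins
#'
#' Affine-gap Needleman-Wunsch with deterministic tie-breaking: at equal
#' score, match/mismatch is preferred over a gap in the candidate, which is
#' preferred over a gap in the reference.
#'
#' @param ref,cand Protein strings (standard residues plus `X`).
#' @param scoring A [scoring_scheme()].
#' @return An `alignment_pair`: list with `ref_aligned`, `cand_aligned`
#'   (equal-length gapped strings) and `score`.
#' @export
#' @examples
#' align_global("MKT", "MT")
align_global <- function(ref, cand, scoring = scoring_scheme()) {
  stopifnot(is.character(ref), length(ref) == 1L,
            is.character(cand), length(cand) == 1L)
  if (!nzchar(ref) || !nzchar(cand)) stop("cannot align an empty sequence")
  alpha <- rownames(scoring$substitution_matrix)
  rc <- chars(ref); cc <- chars(cand)
  ri <- match(rc, alpha); ci <- match(cc, alpha)
  if (anyNA(ri)) stop("unknown character(s) in reference: ",
                      paste(unique(rc[is.na(ri)]), collapse = ", "))
  if (anyNA(ci)) stop("unknown character(s) in candidate: ",
                      paste(unique(cc[is.na(ci)]), collapse = ", "))
  res <- .nw_affine(ri - 1L, ci - 1L, scoring$substitution_matrix,
                    scoring$gap_open, scoring$gap_extend)
  to_str <- function(idx) {
    out <- rep("-", length(idx))
    ok <- idx >= 0L
    out[ok] <- alpha[idx[ok] + 1L]
    paste(out, collapse = "")
  }
  structure(list(ref_aligned = to_str(res$ref_idx),
                 cand_aligned = to_str(res$cand_idx),
                 score = res$score),
            class = "alignment_pair")
}

#' @export
print.alignment_pair <- function(x, ...) {
  cat("Global alignment (score ", x$score, ")\n", sep = "")
  cat("ref:  ", x$ref_aligned, "\n", sep = "")
  cat("cand: ", x$cand_aligned, "\n", sep = "")
  invisible(x)
}

#' Map reference positions to candidate positions
#'
#' @param pair An `alignment_pair` (or any list with `ref_aligned`,
#'   `cand_aligned`). Columns gapped in both rows (possible when the pair is
#'   cut out of a larger multiple alignment) are skipped.
#' @return Integer vector `map` of length `nchar(ungapped reference)`;
#'   `map[i]` is the 1-based candidate position aligned to reference
#'   position `i`, or `NA` where the candidate has a gap.
#' @export
build_position_map <- function(pair) {
  rc <- chars(pair$ref_aligned)
  cc <- chars(pair$cand_aligned)
  stopifnot(length(rc) == length(cc))
  keep <- !(rc == "-" & cc == "-")
  rc <- rc[keep]; cc <- cc[keep]
  n_ref <- sum(rc != "-")
  map <- rep(NA_integer_, n_ref)
  ri <- 0L; ci <- 0L
  for (k in seq_along(rc)) {
    r_gap <- rc[k] == "-"; c_gap <- cc[k] == "-"
    if (!c_gap) ci <- ci + 1L
    if (!r_gap) {
      ri <- ri + 1L
      if (!c_gap) map[ri] <- ci
    }
  }
  map
}

#' Export a position map as TSV
#'
#' @param map Integer vector from [build_position_map()].
#' @param path Output path. Columns: `ref_pos`, `cand_pos` (`NA` for absent).
#' @export
write_position_map <- function(map, path) {
  write.table(data.frame(ref_pos = seq_along(map), cand_pos = map),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Family reference with anchor position
#'
#' Bundles a reference protein, its 1-based substrate-preference anchor
#' position and the family label. The packaged defaults are synthetic toy
#' references (see [toy_reference()]) carrying the anchor and all screened
#' features at the canonical Arabidopsis-numbered positions (DFR 133,
#' FLS 132).
#'
#' @param family `"FLS"` or `"DFR"`.
#' @param reference_protein Reference protein string; defaults to the
#'   packaged synthetic toy reference for the family.
#' @param anchor_position 1-based anchor position in the reference
#'   (defaults: DFR 133, FLS 132).
#' @param reference_id Identifier for the reference sequence.
#' @return A `reference_anchor` list.
#' @export
reference_anchor <- function(family = c("FLS", "DFR"), reference_protein = NULL,
                             anchor_position = NULL, reference_id = NULL) {
  family <- match.arg(family)
  if (is.null(reference_protein)) {
    reference_protein <- toy_reference(family)
    reference_id <- reference_id %||% paste0(family, "_ref_synthetic")
  }
  anchor_position <- anchor_position %||% if (family == "DFR") 133L else 132L
  reference_id <- reference_id %||% paste0(family, "_ref")
  anchor_position <- as.integer(anchor_position)
  stopifnot(anchor_position >= 1L, anchor_position <= nchar(reference_protein))
  structure(list(family = family, reference_id = reference_id,
                 reference_protein = reference_protein,
                 anchor_position = anchor_position),
            class = "reference_anchor")
}

#' Residue of a candidate at the reference anchor
#'
#' @param cand Candidate protein string (ungapped).
#' @param map Position map built against `anchor$reference_protein`.
#' @param anchor A [reference_anchor()].
#' @return Single upper-case residue, or `NA_character_` when the anchor
#'   column is deleted in the candidate.
#' @export
residue_at_anchor <- function(cand, map, anchor) {
  stopifnot(inherits(anchor, "reference_anchor"),
            length(map) == nchar(anchor$reference_protein))
  p <- map[anchor$anchor_position]
  if (is.na(p)) return(NA_character_)
  toupper(substr(cand, p, p))
}

#' Candidate residues over a reference-numbered region
#'
#' @param cand Candidate protein string.
#' @param map Position map against the reference.
#' @param start_ref,end_ref 1-based reference positions, `start_ref <= end_ref`.
#' @return String of length `end_ref - start_ref + 1`; `-` marks reference
#'   columns deleted in the candidate.
#' @export
extract_region <- function(cand, map, start_ref, end_ref) {
  start_ref <- as.integer(start_ref); end_ref <- as.integer(end_ref)
  if (start_ref > end_ref) stop("start_ref (", start_ref, ") > end_ref (", end_ref, ")")
  if (start_ref < 1L || end_ref > length(map)) {
    stop("region ", start_ref, "..", end_ref, " outside reference 1..", length(map))
  }
  pos <- map[start_ref:end_ref]
  out <- rep("-", length(pos))
  ok <- !is.na(pos)
  out[ok] <- chars(cand)[pos[ok]]
  paste(out, collapse = "")
}

#' Drop low-occupancy alignment columns
#'
#' Removes columns whose non-gap fraction is strictly below
#' `min_occupancy` (boundary rule: occupancy exactly at the threshold is
#' kept). The kept-column index allows anchors to be re-located in the
#' cleaned alignment.
#'
#' @param msa Character vector of equal-length aligned sequences.
#' @param min_occupancy Fraction in (0, 1]; default 0.1.
#' @return List with `msa` (cleaned rows, names preserved) and `kept`
#'   (original indices of retained columns).
#' @export
clean_columns <- function(msa, min_occupancy = 0.1) {
  stopifnot(length(msa) >= 1L, min_occupancy > 0, min_occupancy <= 1)
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  occ <- colMeans(m != "-")
  kept <- which(occ >= min_occupancy)
  out <- apply(m[, kept, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(msa)
  list(msa = out, kept = kept)
}
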