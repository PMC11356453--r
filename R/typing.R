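# Residue and motif screening, and substrate-preference classification.
#
# The classification keys on the single anchor residue: DFR position 133
# (N / D / A types) and FLS position 132 (H / F / Y types), in Arabidopsis
# reference numbering. Functionality screening checks the residues and
# motifs known to be required for each family; any failed check marks the
# sequence as a non-functional "-like" candidate.

config_env <- new.env(parent = emptyenv())

read_config_tsv <- function(name) {
  path <- system.file("extdata", name, package = "flavotype", mustWork = TRUE)
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Shipped configuration tables
#'
#' `default_classification()` returns the residue-to-type/substrate lookup;
#' `default_rules(family)` the per-position residue rules;
#' `default_motifs(family)` the motif patterns. All are plain data frames
#' read from editable TSV files under `inst/extdata` and can be replaced by
#' user tables of the same shape.
#'
#' @return A data frame.
#' @export
default_classification <- function() {
  if (is.null(config_env$classification)) {
    config_env$classification <- read_config_tsv("anchor_classification.tsv")
  }
  config_env$classification
}

#' @rdname default_classification
#' @param family `"FLS"` or `"DFR"`.
#' @export
default_rules <- function(family = c("FLS", "DFR")) {
  family <- match.arg(family)
  read_config_tsv(paste0(tolower(family), "_residue_rules.tsv"))
}

#' @rdname default_classification
#' @export
default_motifs <- function(family = c("FLS", "DFR")) {
  family <- match.arg(family)
  read_config_tsv(paste0(tolower(family), "_motifs.tsv"))
}

#' Classify a sequence by its anchor residue
#'
#' Total function over residue x family. DFR: N accepts all three
#' dihydroflavonols, D accepts DHQ and DHM, A prefers DHK, L (reported
#' substitution) restricts to DHK but is labelled `DFR_other`; anything
#' else is `DFR_other` with an empty substrate set. FLS: H/F/Y map to the
#' three FLS types with hypothesized substrate preferences. A deleted
#' anchor (`NA`) is typed `"absent"`, never `"other"`.
#'
#' @param family `"FLS"` or `"DFR"`.
#' @param residue Single residue character, or `NA` for a deleted anchor.
#' @param table Classification table (see [default_classification()]).
#' @return List with `type_label`, `substrates` (character vector, possibly
#'   empty) and `confidence` (`"reported"`, `"hypothesized"` or `"none"`).
#' @export
#' @examples
#' classify_anchor("DFR", "N")
#' classify_anchor("FLS", "V")
classify_anchor <- function(family, residue, table = default_classification()) {
  if (!family %in% c("FLS", "DFR")) stop("unknown family: ", family)
  if (is.na(residue) || residue == "-") {
    return(list(type_label = "absent", substrates = character(0), confidence = "none"))
  }
  stopifnot(is.character(residue), nchar(residue) == 1L)
  residue <- toupper(residue)
  hit <- table[table$family == family & table$residue == residue, , drop = FALSE]
  if (nrow(hit) == 1L) {
    return(list(type_label = hit$type_label,
                substrates = strsplit(hit$substrates, ",", fixed = TRUE)[[1]],
                confidence = hit$confidence))
  }
  list(type_label = paste0(family, "_other"), substrates = character(0),
       confidence = "none")
}

#' Screen a candidate against per-position residue rules
#'
#' A rule fails when the candidate residue mapped to the rule's reference
#' position is absent (deleted) or not in the rule's allowed set.
#'
#' @param cand Candidate protein string.
#' @param map Position map against the family reference.
#' @param rules Data frame with columns `ref_position`, `allowed` (string of
#'   allowed residues) and `role`.
#' @return List with `functional` (TRUE iff no failures) and `failed`
#'   (data frame `ref_position`, `role`, `observed`; `"ABSENT"` for deletions).
#' @export
screen_rules <- function(cand, map, rules) {
  if (is.null(rules) || nrow(rules) == 0L) {
    return(list(functional = TRUE,
                failed = data.frame(ref_position = integer(0), role = character(0),
                                    observed = character(0), stringsAsFactors = FALSE)))
  }
  cc <- chars(cand)
  obs <- vapply(as.integer(rules$ref_position), function(p) {
    if (p < 1L || p > length(map)) return("ABSENT")
    q <- map[p]
    if (is.na(q)) "ABSENT" else cc[q]
  }, character(1))
  ok <- mapply(function(o, allowed) o != "ABSENT" && grepl(o, allowed, fixed = TRUE),
               obs, rules$allowed)
  failed <- data.frame(ref_position = as.integer(rules$ref_position)[!ok],
                       role = rules$role[!ok], observed = obs[!ok],
                       stringsAsFactors = FALSE)
  list(functional = all(ok), failed = failed)
}

# Turn a motif pattern (residue letters, 'x' wildcards, '[DE]' alternatives,
# one bounded run 'x{min,max}') into a lookahead regex that reports all,
# possibly overlapping, match starts.
motif_regex <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (!grepl("^([A-WYZ]|x(\\{[0-9]+,[0-9]+\\})?|\\[[A-Z]+\\])+$", pattern)) {
    stop("invalid motif pattern: ", pattern)
  }
  rx <- gsub("x\\{([0-9]+),([0-9]+)\\}", ".{\\1,\\2}", pattern)
  rx <- gsub("x", ".", rx, fixed = TRUE)
  # token count >= 2 (a bounded run counts as one token)
  ntok <- length(gregexpr("x\\{[0-9]+,[0-9]+\\}|\\[[A-Z]+\\]|[A-WYZx]",
                          pattern)[[1]])
  if (ntok < 2L) stop("motif pattern too short: ", pattern)
  paste0("(?=", rx, ")")
}

#' Scan a protein for a wildcard motif
#'
#' Patterns are residue letters with `x` wildcards, bracketed alternatives
#' such as `[DE]`, and at most one bounded wildcard run `x{min,max}` (so the
#' ferrous-iron binding motif is written `Hx[DE]x{40,150}H`). Overlapping
#' matches are all reported.
#'
#' @param protein Protein string.
#' @param pattern Motif pattern string.
#' @return Integer vector of 1-based match start positions (possibly empty).
#' @export
#' @examples
#' find_motif("AAPQRSIRTUVEQPZZ", "PxxxIRxxxEQP")  # 3
find_motif <- function(protein, pattern) {
  rx <- motif_regex(pattern)
  hits <- gregexpr(rx, protein, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# Screen the motif table; returns character vector of missing motif names.
screen_motifs <- function(protein, motifs) {
  if (is.null(motifs) || nrow(motifs) == 0L) return(character(0))
  missing <- character(0)
  half <- nchar(protein) %/% 2L
  for (i in seq_len(nrow(motifs))) {
    target <- protein
    if (identical(motifs$scope[i], "cterm")) {
      target <- substr(protein, half + 1L, nchar(protein))
    }
    if (length(find_motif(target, motifs$pattern[i])) == 0L) {
      missing <- c(missing, motifs$name[i])
    }
  }
  missing
}

#' Type a set of sequences against a family reference
#'
#' Full per-sequence pipeline: translation (CDS input is auto-detected),
#' global alignment to the reference, anchor-residue extraction,
#' classification, residue-rule and motif screening. For DFR the presence
#' of the 26-residue substrate-binding region (reference positions
#' anchor-2 .. anchor+23) with at most `max_region_gap_fraction` deletions
#' is part of the functional screen. A sequence fails the screen (and is
#' reported as a non-functional "-like" candidate) if any check fails,
#' including an internal stop codon in a CDS input.
#'
#' @param records Named character vector of sequences (proteins, or CDS
#'   which are translated first; a `molecule` attribute as set by
#'   [read_fasta()] overrides auto-detection).
#' @param anchor A [reference_anchor()].
#' @param rules Residue rules (default: [default_rules()] for the family).
#' @param motifs Motif table (default: [default_motifs()] for the family).
#' @param scoring A [scoring_scheme()].
#' @param classification Classification table.
#' @param max_region_gap_fraction Maximum tolerated gap fraction in the DFR
#'   substrate-binding region (default 0.3).
#' @return Data frame of class `typing_result`: one row per input with
#'   `seq_id`, `family`, `anchor_residue` (`NA` when deleted), `type_label`,
#'   `substrates`, `confidence`, `functional`, `failed_checks`,
#'   `internal_stop`.
#' @export
type_sequences <- function(records, anchor, rules = NULL, motifs = NULL,
                           scoring = scoring_scheme(),
                           classification = default_classification(),
                           max_region_gap_fraction = 0.3) {
  stopifnot(inherits(anchor, "reference_anchor"))
  fam <- anchor$family
  if (is.null(rules)) rules <- default_rules(fam)
  if (is.null(motifs)) motifs <- default_motifs(fam)
  empty <- data.frame(seq_id = character(0), family = character(0),
                      anchor_residue = character(0), type_label = character(0),
                      substrates = character(0), confidence = character(0),
                      functional = logical(0), failed_checks = character(0),
                      internal_stop = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("typing_result", "data.frame")
  if (length(records) == 0L) return(empty)
  stopifnot(!is.null(names(records)), all(nzchar(names(records))))

  molecule <- attr(records, "molecule")
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    s <- toupper(records[[i]])
    is_cds <- if (!is.null(molecule)) molecule == "cds" else grepl("^[ACGTN]+$", s)
    internal_stop <- FALSE
    if (is_cds) {
      prot <- translate_cds(s)
      internal_stop <- attr(prot, "internal_stop")
      prot <- as.character(prot)
    } else {
      prot <- s
    }
    prot_clean <- gsub("*", "X", prot, fixed = TRUE) # stops align as neutral X
    pair <- align_global(anchor$reference_protein, prot_clean, scoring)
    map <- build_position_map(pair)
    res <- residue_at_anchor(prot_clean, map, anchor)
    cls <- classify_anchor(fam, res, classification)

    scr <- screen_rules(prot_clean, map, rules)
    failed <- character(0)
    if (nrow(scr$failed) > 0L) {
      failed <- paste0("pos", scr$failed$ref_position, "=", scr$failed$observed)
    }
    missing_motifs <- screen_motifs(prot_clean, motifs)
    if (length(missing_motifs)) failed <- c(failed, paste0("motif:", missing_motifs))
    if (fam == "DFR") {
      lo <- anchor$anchor_position - 2L
      hi <- anchor$anchor_position + 23L
      if (lo >= 1L && hi <= length(map)) {
        region <- extract_region(prot_clean, map, lo, hi)
        gap_frac <- mean(chars(region) == "-")
        if (gap_frac > max_region_gap_fraction) {
          failed <- c(failed, sprintf("substrate_region_gaps=%.2f", gap_frac))
        }
      } else {
        failed <- c(failed, "substrate_region_outside_reference")
      }
    }
    if (internal_stop) failed <- c(failed, "internal_stop")

    out[[i]] <- data.frame(
      seq_id = names(records)[i], family = fam,
      anchor_residue = if (is.na(res)) NA_character_ else res,
      type_label = cls$type_label,
      substrates = paste(cls$substrates, collapse = ","),
      confidence = cls$confidence,
      functional = length(failed) == 0L,
      failed_checks = paste(failed, collapse = ";"),
      internal_stop = internal_stop, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("typing_result", "data.frame")
  res
}

#' Write / read typing results as TSV
#'
#' @param results A `typing_result` data frame.
#' @param path Output path.
#' @export
write_typing_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_typing_tsv
#' @export
read_typing_tsv <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("seq_id", "family", "anchor_residue", "type_label", "functional")
  miss <- setdiff(needed, colnames(x))
  if (length(miss)) stop("typing table missing column(s): ", paste(miss, collapse = ", "))
  class(x) <- c("typing_result", "data.frame")
  x
}

#' Per-group residue pattern summary
#'
#' Aggregates typing results by a grouping of sequences (for instance,
#' species mapped to taxonomic orders): counts of each type label, the
#' modal anchor residue(s) and a compact residue pattern such as `"F/Y"`
#' listing observed anchor residues by decreasing frequency (ties
#' alphabetical).
#'
#' @param results A `typing_result` data frame.
#' @param grouping Named character vector mapping `seq_id` to group label.
#'   Sequences without a group are dropped with a warning; group levels with
#'   no sequences are omitted with a warning.
#' @return Data frame with one row per group: `group`, `n`, `type_counts`
#'   (label:count, comma-joined), `modal_residue`, `pattern`.
#' @export
summarize_types <- function(results, grouping) {
  stopifnot(is.character(grouping), !is.null(names(grouping)))
  g <- grouping[results$seq_id]
  if (anyNA(g)) {
    warning("dropping ", sum(is.na(g)), " sequence(s) without a group")
  }
  keep <- !is.na(g)
  res <- results[keep, , drop = FALSE]
  g <- g[keep]
  missing_groups <- setdiff(unique(unname(grouping)), unique(g))
  if (length(missing_groups)) {
    warning("omitting empty group(s): ", paste(missing_groups, collapse = ", "))
  }
  rows <- lapply(sort(unique(g)), function(grp) {
    sub <- res[g == grp, , drop = FALSE]
    tc <- sort(table(sub$type_label), decreasing = TRUE)
    resid <- sub$anchor_residue[!is.na(sub$anchor_residue)]
    if (length(resid)) {
      rc <- table(resid)
      rc <- rc[order(-rc, names(rc))]
      modal <- paste(names(rc)[rc == max(rc)], collapse = "/")
      pattern <- paste(names(rc), collapse = "/")
    } else {
      modal <- NA_character_; pattern <- NA_character_
    }
    data.frame(group = grp, n = nrow(sub),
               type_counts = paste(names(tc), tc, sep = ":", collapse = ","),
               modal_residue = modal, pattern = pattern, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
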