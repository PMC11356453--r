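# Sequence, tree and abundance-table I/O plus CDS translation.
#
# Sequences travel through the package as named character vectors (one
# element per record, names are record ids) with a "molecule" attribute of
# "cds" or "protein".

#' Read a FASTA file
#'
#' Reads plain or line-wrapped FASTA into a named character vector of
#' upper-cased sequences. Record ids (the first whitespace-delimited token of
#' each header) must be unique within the file.
#'
#' @param path Path to a FASTA file.
#' @param molecule `"auto"` (default), `"cds"` or `"protein"`. Under
#'   `"auto"`, a file whose residues are all in `A,C,G,T,N` is called CDS.
#'   CDS records are validated against that alphabet.
#' @param species Optional species label stored as an attribute.
#' @return Named character vector with attributes `molecule` and `species`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ATGGCC", ">b", "ATGTTT"), f)
#' read_fasta(f)
read_fasta <- function(path, molecule = c("auto", "cds", "protein"),
                       species = NA_character_) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (molecule == "auto") {
    molecule <- if (all(grepl("^[ACGTN]*$", seqs))) "cds" else "protein"
  }
  if (molecule == "cds" && any(bad <- !grepl("^[ACGTN]*$", seqs))) {
    stop("CDS record(s) with non-nucleotide characters: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  structure(seqs, molecule = molecule, species = species)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code. The CDS length must be a multiple of three. A
#' single trailing stop codon is stripped silently; internal stops are kept
#' as `*` and flagged. Codons containing `N` translate to `X`.
#'
#' @param cds A single CDS string (A/C/G/T/N).
#' @return The protein as a length-one character vector carrying a logical
#'   attribute `internal_stop`.
#' @export
#' @examples
#' translate_cds("ATGGCC")            # "MA"
#' translate_cds("ATGTGATTT")         # "M*F", internal stop flagged
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (!grepl("^[ACGTN]*$", cds)) stop("CDS contains non-nucleotide characters")
  n <- nchar(cds)
  if (n == 0L) stop("empty CDS")
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3 (frame error)")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  if (length(aa) > 1L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  structure(paste(aa, collapse = ""), internal_stop = any(aa == "*"))
}

#' Translate a set of coding sequences
#'
#' Vectorised wrapper around [translate_cds()].
#'
#' @param cds_set Named character vector of CDS.
#' @return List with `proteins` (named character vector) and `flags`
#'   (data frame of `seq_id`, `internal_stop`).
#' @export
translate_set <- function(cds_set) {
  prot <- vapply(cds_set, function(s) as.character(translate_cds(s)), character(1))
  flags <- vapply(cds_set, function(s) attr(translate_cds(s), "internal_stop"), logical(1))
  list(proteins = prot,
       flags = data.frame(seq_id = names(cds_set), internal_stop = unname(flags),
                          stringsAsFactors = FALSE))
}

#' Extract the codon encoding a protein position
#'
#' Protein positions are 1-based; codon `p` occupies CDS nucleotides
#' `3(p-1)+1 .. 3p`.
#'
#' @param cds A single CDS string.
#' @param protein_position 1-based position in the translated protein.
#' @return Three-character codon.
#' @export
#' @examples
#' codon_at("ATGGCC", 2)  # "GCC"
codon_at <- function(cds, protein_position) {
  stopifnot(is.character(cds), length(cds) == 1L)
  p <- as.integer(protein_position)
  if (is.na(p) || p < 1L || p > nchar(cds) %/% 3L) {
    stop("protein position ", protein_position, " out of range for CDS of length ",
         nchar(cds))
  }
  substr(cds, 3L * (p - 1L) + 1L, 3L * p)
}

#' Read a kallisto-dialect abundance table
#'
#' Expects the exact tab-separated header
#' `target_id  length  eff_length  est_counts  tpm`.
#'
#' @param path Path to an `abundance.tsv`-style file.
#' @return Data frame with those five columns; `est_counts` and `tpm` are
#'   validated to be non-negative.
#' @export
read_abundance_tsv <- function(path) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  expected <- c("target_id", "length", "eff_length", "est_counts", "tpm")
  if (!identical(header, expected)) {
    stop("abundance table dialect error in ", path, ": header must be exactly {",
         paste(expected, collapse = ", "), "}, got {",
         paste(header, collapse = ", "), "}")
  }
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("length", "eff_length", "est_counts", "tpm")) {
    x[[col]] <- as.numeric(x[[col]])
    if (anyNA(x[[col]])) stop("non-numeric value in column ", col, " of ", path)
  }
  if (any(x$est_counts < 0) || any(x$tpm < 0)) {
    bad <- x$target_id[x$est_counts < 0 | x$tpm < 0]
    stop("negative abundance value(s) for: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(x$target_id)) stop("duplicate target_id in ", path)
  x
}

#' Write a kallisto-dialect abundance table
#'
#' @param x Data frame with columns `target_id`, `length`, `eff_length`,
#'   `est_counts`, `tpm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  expected <- c("target_id", "length", "eff_length", "est_counts", "tpm")
  stopifnot(identical(colnames(x), expected))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that preserve
#' topology, tip labels, branch lengths and internal support labels.
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
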