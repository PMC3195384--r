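# Per-site variability accounting: variable-site counts at nucleotide and
# amino-acid level, partition-stratified polymorphism, per-position residue
# repertoires and the pairwise identity range.

# character matrix (rows = sequences) from an allele_set or string vector
seq_char_matrix <- function(x) {
  seqs <- if (inherits(x, "allele_set")) x$sequences else as.character(x)
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  t(vapply(seqs, function(s) strsplit(s, "")[[1]], character(lens[1L])))
}

.missing_nt <- c("-", "N")
.missing_aa <- c("-", "X")

col_is_variable <- function(m, missing_symbols) {
  apply(m, 2L, function(col) {
    obs <- unique(col[!col %in% missing_symbols])
    length(obs) >= 2L
  })
}

#' Count variable columns in an alignment
#'
#' A column is variable iff at least two distinct non-missing symbols occur
#' in it (missing: `-`/`N` at nucleotide level, `-`/`X` at amino-acid
#' level; stop `*` is a concrete symbol).
#'
#' @param x An [allele_set()] (translated internally for
#'   `level = "amino_acid"`) or a character vector of equal-length strings.
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @return List with `variable`, `total` and `fraction`.
#' @export
variable_sites <- function(x, level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  if (inherits(x, "allele_set") && level == "amino_acid")
    x <- translate_alleles(x)
  m <- seq_char_matrix(x)
  miss <- if (level == "nucleotide") .missing_nt else .missing_aa
  v <- sum(col_is_variable(m, miss))
  list(variable = v, total = ncol(m), fraction = v / ncol(m))
}

#' Partition-stratified amino-acid variability
#'
#' Applies the variable-site rule within the PBR and non-PBR strata of a
#' codon partition.
#'
#' @param residues Character vector of amino-acid strings with length equal
#'   to `partition$total` residues each (e.g. from [translate_alleles()]).
#' @param partition A [codon_partition()].
#' @return List with `pbr_variable`, `pbr_total`, `nonpbr_variable`,
#'   `nonpbr_total` and the corresponding `*_fraction`s.
#' @export
partition_variability <- function(residues, partition) {
  stopifnot(inherits(partition, "codon_partition"))
  if (inherits(residues, "allele_set")) residues <- translate_alleles(residues)
  m <- seq_char_matrix(residues)
  if (ncol(m) != partition$total)
    stop("residue length ", ncol(m), " does not match partition total ",
         partition$total, call. = FALSE)
  v <- col_is_variable(m, .missing_aa)
  np <- nonpbr_indices(partition)
  list(pbr_variable = sum(v[partition$pbr]),
       pbr_total = length(partition$pbr),
       nonpbr_variable = sum(v[np]),
       nonpbr_total = length(np),
       pbr_fraction = if (length(partition$pbr))
         sum(v[partition$pbr]) / length(partition$pbr) else NA_real_,
       nonpbr_fraction = if (length(np)) sum(v[np]) / length(np)
       else NA_real_)
}

#' Per-position amino-acid repertoires
#'
#' For every codon position, the sorted set of amino acids observed across
#' the panel (missing `X`/`-` excluded; alphabetical order within a set).
#' Monomorphic positions render as a single residue.
#'
#' @inheritParams partition_variability
#' @param residue_offset Added to positions for display (8 maps alignment
#'   codon 1 to mature-protein residue 9 in the standard exon-2 window).
#' @return Object of class `polymorphism_table`: data frame with columns
#'   `position`, `is_pbr`, `residues`, plus attributes `n_sequences` and
#'   `residue_offset`.
#' @export
residue_table <- function(residues, partition, residue_offset = 0L) {
  stopifnot(inherits(partition, "codon_partition"))
  if (inherits(residues, "allele_set")) residues <- translate_alleles(residues)
  m <- seq_char_matrix(residues)
  if (ncol(m) != partition$total)
    stop("residue length ", ncol(m), " does not match partition total ",
         partition$total, call. = FALSE)
  sets <- apply(m, 2L, function(col) {
    paste(sort(unique(col[!col %in% .missing_aa])), collapse = "")
  })
  out <- data.frame(position = seq_len(partition$total) + residue_offset,
                    is_pbr = seq_len(partition$total) %in% partition$pbr,
                    residues = unname(sets), stringsAsFactors = FALSE)
  attr(out, "n_sequences") <- nrow(m)
  attr(out, "residue_offset") <- residue_offset
  class(out) <- c("polymorphism_table", "data.frame")
  out
}

#' @export
print.polymorphism_table <- function(x, ...) {
  cat("Per-position amino-acid repertoires (",
      attr(x, "n_sequences"), " sequences; * = PBR)\n", sep = "")
  lab <- paste0(ifelse(x$is_pbr, "*", " "),
                formatC(x$position, width = 3))
  cat(paste0(lab, "  ", x$residues), sep = "\n")
  invisible(x)
}

#' Pairwise percent-identity matrix
#'
#' Identity between two sequences is the percentage of matching columns over
#' columns comparable in both (pairwise deletion of `-`/`N`). The minimum
#' and maximum over all unordered pairs are attached as attributes and are
#' conventionally reported rounded to the nearest integer.
#'
#' @param x An [allele_set()] with at least 2 sequences.
#' @return Symmetric numeric matrix (diagonal 100) with attributes `min` and
#'   `max` over off-diagonal pairs.
#' @export
identity_matrix <- function(x) {
  stopifnot(inherits(x, "allele_set"))
  m <- seq_char_matrix(x)
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(x$ids, x$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !(m[i, ] %in% .missing_nt) & !(m[j, ] %in% .missing_nt)
    out[i, j] <- out[j, i] <-
      if (any(ok)) 100 * mean(m[i, ok] == m[j, ok]) else NA_real_
  }
  off <- out[lower.tri(out)]
  attr(out, "min") <- min(off, na.rm = TRUE)
  attr(out, "max") <- max(off, na.rm = TRUE)
  out
}
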