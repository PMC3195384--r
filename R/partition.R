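#' Construct a codon partition (peptide-binding-region mask)
#'
#' A `codon_partition` designates which 1-based codon positions of an
#' alignment belong to the peptide-binding region (PBR); the remaining
#' positions form the non-PBR complement. Positions are indexed in alignment
#' coordinates (`1..total`). For the standard 78-codon DRB exon-2 window the
#' first alignment codon corresponds to mature-protein residue 9, so reports
#' can add a residue-number offset (see `residue_offset` arguments).
#'
#' @param total Total number of codons in the alignment.
#' @param pbr Integer vector of 1-based PBR codon positions (no duplicates,
#'   all within `1..total`).
#' @param name Free-text mask name.
#' @return Object of class `codon_partition` with fields `name`, `total`
#'   and sorted `pbr`.
#' @export
codon_partition <- function(total, pbr, name = "") {
  total <- as.integer(total)
  pbr <- as.integer(pbr)
  if (total < 1L) stop("total codon count must be positive", call. = FALSE)
  if (anyDuplicated(pbr))
    stop("duplicate PBR positions in mask", call. = FALSE)
  if (length(pbr) && (min(pbr) < 1L || max(pbr) > total))
    stop("PBR positions must lie in 1..", total, call. = FALSE)
  structure(list(name = name, total = total, pbr = sort(pbr)),
            class = "codon_partition")
}

#' @export
print.codon_partition <- function(x, ...) {
  cat("Codon partition", if (nzchar(x$name)) paste0("'", x$name, "'"), ":",
      length(x$pbr), "PBR /", x$total - length(x$pbr), "non-PBR of",
      x$total, "codons\n")
  cat("  PBR:", paste(x$pbr, collapse = ","), "\n")
  invisible(x)
}

#' Complement (non-PBR) positions of a partition
#' @param partition A `codon_partition`.
#' @return Sorted integer vector of non-PBR codon positions.
#' @export
nonpbr_indices <- function(partition) {
  setdiff(seq_len(partition$total), partition$pbr)
}

#' Load a codon-partition mask file
#'
#' Plain-text format: line 1 `total=<n>`, line 2 comma-separated 1-based PBR
#' codon positions. A single-line `"<n>; p1,p2,..."` form is also accepted.
#'
#' @param path Path to the mask file.
#' @return A [codon_partition()].
#' @export
load_partition <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  txt <- gsub("total\\s*=", "", txt)
  nums <- suppressWarnings(as.integer(
    regmatches(txt, gregexpr("[0-9]+", txt))[[1]]))
  if (length(nums) < 1L || anyNA(nums))
    stop("cannot parse mask file: ", path, call. = FALSE)
  codon_partition(nums[1L], nums[-1L],
                  name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a codon-partition mask file
#' @param partition A `codon_partition`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(partition, path) {
  writeLines(c(paste0("total=", partition$total),
               paste(partition$pbr, collapse = ",")), path)
  invisible(path)
}

# Residue-numbered PBR assignments for the 78-codon DRB exon-2 window
# (mature-protein residues 9..86, i.e. alignment codon = residue - 8).
.mask_table2_residues <- c(9, 11, 13, 28, 30, 32, 37, 38, 47, 56, 60, 61,
                           70, 71, 74, 78, 81, 82, 85, 86)
.mask_brown22_residues <- sort(c(.mask_table2_residues, 26, 65))

#' Bundled peptide-binding-region masks
#'
#' Two masks for the standard 78-codon DRB exon-2 alignment (mature-protein
#' residues 9-86) are shipped, reflecting two defensible readings of the
#' Brown et al. (1993) human DR contact-residue model:
#'
#' * `"table2-asterisks"` — the 20 residues conventionally starred in
#'   interspecies DRB polymorphism tables (9, 11, 13, 28, 30, 32, 37, 38,
#'   47, 56, 60, 61, 70, 71, 74, 78, 81, 82, 85, 86).
#' * `"brown1993-22"` — those 20 plus contact residues 26 and 65, giving the
#'   22-codon PBR stratum used in selection reports (positions 57 and 67,
#'   also peptide contacts in some renderings, are conventionally treated as
#'   non-PBR in ruminant DRB work and are excluded here).
#'
#' Both are returned in alignment coordinates (1..78).
#'
#' @param name `"table2-asterisks"` or `"brown1993-22"`.
#' @return A [codon_partition()] with 78 total codons.
#' @export
bundled_partition <- function(name = c("brown1993-22", "table2-asterisks")) {
  name <- match.arg(name)
  res <- switch(name,
                "table2-asterisks" = .mask_table2_residues,
                "brown1993-22" = .mask_brown22_residues)
  codon_partition(78L, res - 8L, name = name)
}

#' Split an alignment into PBR and non-PBR sub-alignments
#'
#' Returns two allele sets whose sequences are the concatenated PBR codons
#' and the concatenated non-PBR codons, original codon order preserved
#' within each. The codon indices drawn into each half are recorded in the
#' `"codon_indices"` attribute so the original alignment can be reassembled.
#'
#' @param x An [allele_set()].
#' @param partition A [codon_partition()] with
#'   `3 * partition$total == x$length`.
#' @return List with elements `pbr` and `nonpbr`.
#' @export
split_codons <- function(x, partition) {
  stopifnot(inherits(x, "allele_set"), inherits(partition, "codon_partition"))
  if (x$length != 3L * partition$total)
    stop("partition covers ", partition$total, " codons but alignment has ",
         x$length %/% 3L, call. = FALSE)
  take <- function(idx) {
    seqs <- vapply(x$sequences, function(s) {
      if (length(idx) == 0L) return("")
      paste(substring(s, 3L * idx - 2L, 3L * idx), collapse = "")
    }, "", USE.NAMES = FALSE)
    out <- allele_set(x$ids, seqs, x$label)
    attr(out, "codon_indices") <- idx
    out
  }
  list(pbr = take(partition$pbr), nonpbr = take(nonpbr_indices(partition)))
}

# restrict an allele_set to the given codon positions (internal fast path)
subset_codons <- function(x, idx) {
  if (length(idx) == x$length %/% 3L && all(idx == seq_along(idx))) return(x)
  seqs <- vapply(x$sequences, function(s)
    paste(substring(s, 3L * idx - 2L, 3L * idx), collapse = ""),
    "", USE.NAMES = FALSE)
  allele_set(x$ids, seqs, x$label)
}
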