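#' Construct an allele set
#'
#' An `allele_set` is a named collection of equal-length, aligned coding
#' nucleotide sequences for one species or breed panel (e.g. the curated
#' BoLA-DRB3 exon-2 alleles of a cattle population). Sequences are stored
#' uppercase over the alphabet `A,C,G,T,-,N`; `U` is rewritten to `T` and any
#' other IUPAC ambiguity code is mapped to `N` with a warning.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param sequences Character vector of aligned nucleotide strings, parallel
#'   to `ids`. All must have the same length, a positive multiple of 3.
#' @param label Free-text panel label (species/breed), default `""`.
#' @return An object of class `allele_set` with fields `label`, `ids`,
#'   `sequences` and `length` (alignment length in nucleotides).
#' @examples
#' x <- allele_set(c("a", "b"), c("ACGACG", "ACTACG"), label = "demo")
#' x$length
#' @export
allele_set <- function(ids, sequences, label = "") {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("ids and sequences must have the same length", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  if (any(grepl("[^ACGTN-]", sequences))) {
    warning("ambiguity codes other than N mapped to N", call. = FALSE)
    sequences <- gsub("[^ACGTN-]", "N", sequences)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("unequal sequence lengths in alignment (record '", bad, "')",
         call. = FALSE)
  }
  # zero length is tolerated so empty partition strata remain representable
  len <- lens[1L]
  if (len %% 3L != 0L)
    stop("alignment length must be a multiple of 3, got ", len,
         call. = FALSE)
  structure(list(label = label, ids = ids, sequences = sequences,
                 length = len),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("Allele set", if (nzchar(x$label)) paste0("'", x$label, "'"), "—",
      length(x$ids), "sequences x", x$length, "nt (",
      x$length %/% 3L, "codons )\n")
  show <- utils::head(x$ids, 6L)
  cat("  ids:", paste(show, collapse = ", "),
      if (length(x$ids) > 6L) "...", "\n")
  invisible(x)
}

#' @export
length.allele_set <- function(x) length(x$ids)

#' Subset an allele set by index or id
#' @param x An `allele_set`.
#' @param i Integer, logical or character (id) index.
#' @param ... Ignored.
#' @export
`[.allele_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  allele_set(x$ids[i], x$sequences[i], x$label)
}

#' Read an aligned FASTA file into an allele set
#'
#' Records must all have the same length (it is an alignment) and the length
#' must be a multiple of 3. Case and `U`/`T` are normalized on read.
#'
#' @param path Path to an aligned FASTA file with at least 2 records.
#' @param label Panel label; defaults to the file name without extension.
#' @return An [allele_set()].
#' @export
read_aligned_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  if (length(recs) < 2L)
    stop("FASTA must contain at least 2 records: ", path, call. = FALSE)
  if (any(nchar(vapply(recs, as.character, "")) == 0L))
    stop("empty FASTA record in ", path, call. = FALSE)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  allele_set(names(recs), vapply(recs, as.character, ""), label)
}

#' Write an allele set as aligned FASTA (wrapped at 60 columns)
#' @param x An `allele_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_aligned_fasta <- function(x, path) {
  seqinr::write.fasta(as.list(x$sequences), names = x$ids,
                      file.out = path, nbchar = 60, as.string = TRUE)
  invisible(path)
}

#' Trim an alignment to a nucleotide window
#'
#' Cuts every sequence to the window `[start, start + length - 1]`, the
#' operation used to standardize exon-2 panels to a uniform 234-bp region.
#'
#' @param x An `allele_set`.
#' @param start 1-based nucleotide position of the window start.
#' @param length Window length in nucleotides, a multiple of 3.
#' @return The trimmed `allele_set`; label and ids preserved.
#' @export
trim_to_region <- function(x, start, length) {
  stopifnot(inherits(x, "allele_set"))
  if (start < 1L) stop("start must be >= 1", call. = FALSE)
  if (length %% 3L != 0L)
    stop("window length must be a multiple of 3", call. = FALSE)
  end <- start + length - 1L
  if (end > x$length)
    stop("window [", start, ", ", end, "] exceeds alignment length ",
         x$length, call. = FALSE)
  allele_set(x$ids, substr(x$sequences, start, end), x$label)
}

#' Remove byte-identical sequences, keeping first occurrences
#'
#' Curation rule used to reduce downloaded allele panels to distinct alleles:
#' exact nucleotide-string comparison after case/U normalization, first
#' occurrence kept, original order preserved. Idempotent.
#'
#' @param x An `allele_set`.
#' @return The deduplicated `allele_set`.
#' @export
dedupe_identical <- function(x) {
  stopifnot(inherits(x, "allele_set"))
  keep <- !duplicated(x$sequences)
  allele_set(x$ids[keep], x$sequences[keep], x$label)
}

#' Translate aligned nucleotide sequences to amino acids
#'
#' Standard genetic code. Codons containing `-` or `N` translate to the
#' missing symbol `X`; stop codons translate to `*` (represented, not
#' rejected).
#'
#' @param x An `allele_set` (or character vector of equal-length sequences).
#' @param frame_offset 0, 1 or 2 nucleotides skipped before the first codon.
#' @return Named character vector of amino-acid strings, one per sequence,
#'   each of length `floor((length - frame_offset) / 3)`.
#' @export
translate_alleles <- function(x, frame_offset = 0L) {
  if (inherits(x, "allele_set")) {
    seqs <- x$sequences
    names(seqs) <- x$ids
  } else seqs <- toupper(x)
  stopifnot(frame_offset %in% 0:2)
  if (any(nchar(seqs) - frame_offset < 3L))
    stop("sequences too short to translate at offset ", frame_offset,
         call. = FALSE)
  vapply(seqs, function(s) {
    n_cod <- (nchar(s) - frame_offset) %/% 3L
    starts <- frame_offset + 1L + 3L * (seq_len(n_cod) - 1L)
    cods <- substring(s, starts, starts + 2L)
    paste(translate_codons(cods), collapse = "")
  }, "", USE.NAMES = TRUE)
}

#' Manifest of an allele set
#'
#' One row per sequence: id, panel label, length and md5 of the sequence
#' string. Written as TSV when `path` is given.
#'
#' @param x An `allele_set`.
#' @param path Optional TSV output path.
#' @return A data frame (invisibly when `path` is given).
#' @export
allele_manifest <- function(x, path = NULL) {
  stopifnot(inherits(x, "allele_set"))
  md5 <- vapply(x$sequences, function(s) {
    tf <- tempfile(); on.exit(unlink(tf))
    writeChar(s, tf, eos = NULL)
    unname(tools::md5sum(tf))
  }, "")
  out <- data.frame(id = x$ids, label = x$label, length = x$length,
                    md5 = unname(md5), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Minimal GenBank flat-file reader
#'
#' Convenience ingestion of locally saved GenBank flat files (LOCUS/ORIGIN
#' records); the canonical interchange format of this package remains aligned
#' FASTA, and no network fetching is performed. Note one published buffalo
#' accession, "AF3854473", carries an extra digit and cannot be resolved to a
#' valid GenBank identifier; such records must be obtained and corrected by
#' the user.
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @param label Panel label for the resulting set.
#' @return An [allele_set()] (sequence order as in the file).
#' @export
read_genbank <- function(path, label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ids <- character(); seqs <- character()
  cur_id <- NULL; cur_seq <- NULL; in_origin <- FALSE
  for (ln in lines) {
    if (grepl("^LOCUS", ln)) {
      cur_id <- strsplit(trimws(ln), "\\s+")[[1]][2]
      cur_seq <- character(); in_origin <- FALSE
    } else if (grepl("^ACCESSION", ln)) {
      acc <- strsplit(trimws(ln), "\\s+")[[1]][2]
      if (!is.na(acc)) cur_id <- acc
    } else if (grepl("^ORIGIN", ln)) {
      in_origin <- TRUE
    } else if (grepl("^//", ln)) {
      if (!is.null(cur_id)) {
        ids <- c(ids, cur_id)
        seqs <- c(seqs, paste(cur_seq, collapse = ""))
      }
      cur_id <- NULL; in_origin <- FALSE
    } else if (in_origin) {
      cur_seq <- c(cur_seq, gsub("[^A-Za-z-]", "", ln))
    }
  }
  if (length(ids) == 0L)
    stop("no GenBank records found in ", path, call. = FALSE)
  allele_set(ids, seqs, label)
}
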