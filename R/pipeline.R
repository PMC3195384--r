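# End-to-end orchestration: per-panel selection reports (Table-1 style),
# interspecies polymorphism tables (Table-2 style) and the pooled
# Neighbor-Joining tree, plus the in-process command-line entry point.

# normalize the panels argument: named list of allele_set, or named
# character vector / list of FASTA paths
resolve_panels <- function(panels) {
  if (inherits(panels, "allele_set")) panels <- list(panels)
  panels <- as.list(panels)
  out <- lapply(seq_along(panels), function(i) {
    p <- panels[[i]]
    if (is.character(p)) p <- read_aligned_fasta(p, label = names(panels)[i])
    stopifnot(inherits(p, "allele_set"))
    nm <- names(panels)[i]
    if (!is.null(nm) && nzchar(nm)) p$label <- nm
    p
  })
  names(out) <- vapply(out, function(p)
    if (nzchar(p$label)) p$label else "panel", "")
  out
}

resolve_mask <- function(mask, n_codons) {
  if (is.null(mask)) return(NULL)
  if (inherits(mask, "codon_partition")) return(mask)
  if (is.character(mask)) {
    if (mask %in% c("brown1993-22", "table2-asterisks"))
      return(bundled_partition(mask))
    return(load_partition(mask))
  }
  stop("mask must be a codon_partition, bundled mask name or file path",
       call. = FALSE)
}

fmt_p <- function(p) sprintf("%.3f", pmin(pmax(p, 0), 1))

#' Selection report over one or more allele panels
#'
#' Runs [dedupe_identical()] then [ng_selection()] per panel and assembles
#' the per-stratum rows (PBR, non-PBR, All) into one table: number of
#' alleles, codon count N, mean pairwise K2P distance, dN(SE), dS(SE),
#' dN/dS and the one-tailed P of the Z-test of positive selection.
#' Distances print with 3 decimals, ratios with 2, P with 3;
#' byte-identical output for a fixed seed.
#'
#' @param panels Named list of [allele_set()] objects or FASTA paths; names
#'   become panel labels.
#' @param mask A [codon_partition()], a bundled mask name
#'   (`"brown1993-22"`, `"table2-asterisks"`) or a mask file path.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Integer master seed.
#' @param out Optional TSV output path.
#' @return Data frame of formatted report rows (invisibly when `out` is
#'   given); the unformatted fits are attached as attribute `"fits"`.
#' @export
run_selection_report <- function(panels, mask = "brown1993-22",
                                 replicates = 1000L, seed = 1L,
                                 out = NULL) {
  panels <- resolve_panels(panels)
  rows <- list(); fits <- list()
  for (nm in names(panels)) {
    p <- dedupe_identical(panels[[nm]])
    partition <- resolve_mask(mask, p$length %/% 3L)
    fit <- tryCatch(ng_selection(p, partition, replicates, seed),
                    error = function(e) {
                      message("panel '", nm, "' failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    fits[[nm]] <- fit
    tab <- ng_selection_table(fit)
    rows[[nm]] <- data.frame(
      Alleles = c(nm, rep("", nrow(tab) - 1L)),
      No_alleles = c(fit$n_alleles, rep("", nrow(tab) - 1L)),
      Positions = tab$stratum, N = tab$n_codons,
      d_K2P = sprintf("%.3f(%.3f)", tab$d_k2p, tab$d_k2p_se),
      dN_SE = sprintf("%.3f(%.3f)", tab$dN, tab$dN_se),
      dS_SE = sprintf("%.3f(%.3f)", tab$dS, tab$dS_se),
      dN_dS = ifelse(is.na(tab$dN_dS), "undef",
                     sprintf("%.2f", tab$dN_dS)),
      P = fmt_p(tab$p), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("every panel failed", call. = FALSE)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "fits") <- fits
  if (!is.null(out)) {
    utils::write.table(report, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Interspecies polymorphism report
#'
#' One row per codon position (asterisk-prefixed when in the PBR), one
#' column per panel holding the sorted amino-acid repertoire at that
#' position, and a bottom row with the panel sizes (`n = ...`). Panels are
#' deduplicated before counting; column order follows input order.
#'
#' @inheritParams run_selection_report
#' @param residue_offset Added to codon positions for display (default 8,
#'   mapping alignment codon 1 to mature-protein residue 9).
#' @return Data frame (invisibly when `out` is given).
#' @export
run_polymorphism_report <- function(panels, mask = "brown1993-22",
                                    residue_offset = 8L, out = NULL) {
  panels <- resolve_panels(panels)
  cols <- list(); ns <- integer()
  positions <- NULL
  for (nm in names(panels)) {
    p <- dedupe_identical(panels[[nm]])
    partition <- resolve_mask(mask, p$length %/% 3L)
    tab <- residue_table(translate_alleles(p), partition,
                         residue_offset = residue_offset)
    if (is.null(positions)) {
      positions <- paste0(ifelse(tab$is_pbr, "*", ""), tab$position)
    }
    cols[[nm]] <- tab$residues
    ns[[nm]] <- attr(tab, "n_sequences")
  }
  body <- data.frame(Codon_position = positions, cols, check.names = FALSE,
                     stringsAsFactors = FALSE)
  bottom <- c("", sprintf("n = %d", ns))
  report <- rbind(body, setNames(as.list(bottom), names(body)))
  if (!is.null(out)) {
    utils::write.table(report, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Pooled Neighbor-Joining tree report
#'
#' Pools all panels (ids prefixed with the panel label when needed to stay
#' unique), deduplicates, translates, applies complete deletion, computes
#' Poisson-corrected distances, builds the NJ tree and bootstrap supports,
#' and writes newick. A saturated pair aborts the run naming the pair.
#'
#' @inheritParams run_selection_report
#' @param out Optional newick output path.
#' @return List with `tree` (a `phylo`), `total_length`,
#'   `retained_columns`, `n_tips` (invisibly when `out` is given).
#' @export
run_tree <- function(panels, replicates = 1000L, seed = 1L, out = NULL) {
  panels <- resolve_panels(panels)
  ids <- character(); seqs <- character()
  for (nm in names(panels)) {
    p <- panels[[nm]]
    pid <- if (length(panels) > 1L) paste0(nm, "_", p$ids) else p$ids
    ids <- c(ids, pid); seqs <- c(seqs, p$sequences)
  }
  pooled <- dedupe_identical(allele_set(ids, seqs, label = "pooled"))
  if (length(pooled$ids) < 3L)
    stop("need at least 3 distinct pooled sequences", call. = FALSE)
  res <- complete_deletion(translate_alleles(pooled))
  tree <- bootstrap_supports(res, replicates = replicates, seed = seed)
  summary <- list(tree = tree,
                  total_length = attr(tree, "total_length"),
                  retained_columns = length(attr(res, "kept_columns")),
                  n_tips = length(tree$tip.label))
  if (!is.null(out)) {
    write_newick(tree, out)
    return(invisible(summary))
  }
  summary
}

#' Run the full analysis pipeline
#'
#' Selection report, polymorphism report and pooled tree in one call,
#' writing `selection.tsv`, `polymorphism.tsv`, `tree.nwk` and
#' `tree_summary.tsv` under `output_dir`.
#'
#' @inheritParams run_selection_report
#' @param output_dir Output directory (created if needed).
#' @param residue_offset Passed to [run_polymorphism_report()].
#' @return Invisibly, a list with the three results.
#' @export
run_analysis <- function(panels, mask = "brown1993-22",
                         replicates = 1000L, seed = 1L,
                         output_dir = ".", residue_offset = 8L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  sel <- run_selection_report(panels, mask, replicates, seed,
                              out = file.path(output_dir, "selection.tsv"))
  pol <- run_polymorphism_report(panels, mask, residue_offset,
                                 out = file.path(output_dir,
                                                 "polymorphism.tsv"))
  tre <- run_tree(panels, replicates, seed,
                  out = file.path(output_dir, "tree.nwk"))
  utils::write.table(
    data.frame(total_length = sprintf("%.8f", tre$total_length),
               retained_columns = tre$retained_columns,
               n_tips = tre$n_tips),
    file.path(output_dir, "tree_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(selection = sel, polymorphism = pol, tree = tre))
}

# ---- command-line front end -------------------------------------------------

parse_cli_args <- function(args) {
  out <- list(panels = character(), flags = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--panel") {
      out$panels <- c(out$panels, args[[i + 1L]]); i <- i + 2L
    } else if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      out$flags[[gsub("-", "_", key)]] <- args[[i + 1L]]; i <- i + 2L
    } else {
      out$cmd <- c(out$cmd, a); i <- i + 1L
    }
  }
  if (!is.null(out$flags$config) && file.exists(out$flags$config)) {
    for (ln in readLines(out$flags$config, warn = FALSE)) {
      ln <- trimws(sub("#.*", "", ln))
      if (!nzchar(ln)) next
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- gsub("-", "_", trimws(kv[1]))
      val <- trimws(paste(kv[-1], collapse = "="))
      if (key == "panel") out$panels <- c(out$panels, val)
      else if (is.null(out$flags[[key]])) out$flags[[key]] <- val
    }
  }
  out
}

#' In-process command-line entry point
#'
#' Subcommands: `simulate`, `selection`, `polymorphism`, `tree`, `all`.
#' Flags: `--panel LABEL=PATH` (repeatable), `--mask`, `--replicates`,
#' `--seed`, `--out`, `--config FILE` (key=value lines with the same keys);
#' `simulate` additionally accepts `--n-alleles`, `--n-codons`,
#' `--omega-pbr`, `--omega-nonpbr`, `--branch-length`. This function backs
#' the installed `pbrselect` script
#' (`system.file("scripts", "pbrselect", package = "pbrselect")`).
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result of the dispatched command.
#' @export
pipeline_cli <- function(args) {
  p <- parse_cli_args(args)
  if (is.null(p$cmd))
    stop("usage: pbrselect <simulate|selection|polymorphism|tree|all> ",
         "[--panel LABEL=PATH]... [--mask M] [--replicates R] [--seed S] ",
         "[--out PATH]", call. = FALSE)
  cmd <- p$cmd[[1L]]
  f <- p$flags
  seed <- as.integer(f$seed %||% 1L)
  replicates <- as.integer(f$replicates %||% 1000L)
  mask <- f$mask %||% "brown1993-22"
  out <- f$out
  panels <- NULL
  if (length(p$panels)) {
    kv <- strsplit(p$panels, "=", fixed = TRUE)
    panels <- setNames(vapply(kv, function(x)
      paste(x[-1], collapse = "="), ""),
      vapply(kv, `[[`, "", 1L))
  }
  res <- switch(
    cmd,
    simulate = {
      cfg <- simulation_config(
        n_alleles = as.integer(f$n_alleles %||% 22L),
        n_codons = as.integer(f$n_codons %||% 78L),
        omega_pbr = as.numeric(f$omega_pbr %||% 3),
        omega_nonpbr = as.numeric(f$omega_nonpbr %||% 1),
        branch_length = as.numeric(f$branch_length %||% 0.4),
        seed = seed)
      panel <- list(alleles = simulate_alleles(cfg),
                    partition = cfg$partition)
      write_fixture(panel, out %||% ".")
    },
    selection = run_selection_report(panels, mask, replicates, seed,
                                     out = out),
    polymorphism = run_polymorphism_report(panels, mask, out = out),
    tree = run_tree(panels, replicates, seed, out = out),
    all = run_analysis(panels, mask, replicates, seed,
                       output_dir = out %||% "."),
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
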