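# Mean pairwise substitution estimates, codon-bootstrap standard errors and
# the Z-test of positive selection.
#
# The workhorse representation is a set of per-pair, per-column matrices
# (differences and site counts for every unordered sequence pair), so the
# point estimate and every bootstrap replicate reduce to rowSums over a
# column index vector.

# codon-level matrices for Nei-Gojobori statistics
ng_pair_matrices <- function(x) {
  tb <- ng_tables()
  n <- length(x$ids)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  ncod <- x$length %/% 3L
  codes <- t(vapply(x$sequences,
                    function(s) codon_codes(split_into_codons(s)),
                    integer(ncod)))
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  SDm <- matrix(NA_real_, np, ncod); NDm <- SDm; Sm <- SDm
  for (p in seq_len(np)) {
    ia <- codes[pairs[1L, p], ]; ib <- codes[pairs[2L, p], ]
    ok <- !is.na(ia) & !is.na(ib)
    SDm[p, ok] <- tb$SD[cbind(ia[ok], ib[ok])]
    NDm[p, ok] <- tb$ND[cbind(ia[ok], ib[ok])]
    Sm[p, ok] <- (tb$syn_sites[ia[ok]] + tb$syn_sites[ib[ok]]) / 2
  }
  list(SD = SDm, ND = NDm, S = Sm, n_pairs = np, n_codons = ncod,
       pairs = pairs, ids = x$ids)
}

# per-pair dN or dS for a codon-column index vector; NA = excluded pair
ng_pair_stat <- function(m, idx, statistic) {
  use <- !is.na(m$S[, idx, drop = FALSE])
  ncmp <- rowSums(use)
  S <- rowSums(m$S[, idx, drop = FALSE], na.rm = TRUE)
  if (statistic == "dS") {
    Sd <- rowSums(m$SD[, idx, drop = FALSE], na.rm = TRUE)
    p <- ifelse(S > 0, Sd / S, ifelse(ncmp > 0, 0, NA_real_))
  } else {
    Nd <- rowSums(m$ND[, idx, drop = FALSE], na.rm = TRUE)
    N <- 3 * ncmp - S
    p <- ifelse(N > 0, Nd / N, ifelse(ncmp > 0, 0, NA_real_))
  }
  p[ncmp == 0L] <- NA_real_
  jc_or_na(p)
}

# nucleotide-level matrices for the K2P distance
k2p_pair_matrices <- function(x) {
  n <- length(x$ids)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  chars <- t(vapply(x$sequences, function(s) strsplit(s, "")[[1]],
                    character(x$length)))
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  TS <- matrix(NA_real_, np, x$length); TV <- TS
  for (p in seq_len(np)) {
    a <- chars[pairs[1L, p], ]; b <- chars[pairs[2L, p], ]
    ok <- a %in% .bases & b %in% .bases
    diff <- ok & a != b
    ts <- diff & (.purine[a] == .purine[b])
    TS[p, ok] <- as.numeric(ts[ok])
    TV[p, ok] <- as.numeric(diff[ok] & !ts[ok])
  }
  list(TS = TS, TV = TV, n_pairs = np, pairs = pairs, ids = x$ids)
}

k2p_pair_stat <- function(m, idx) {
  use <- !is.na(m$TS[, idx, drop = FALSE])
  ncmp <- rowSums(use)
  P <- rowSums(m$TS[, idx, drop = FALSE], na.rm = TRUE) / ncmp
  Q <- rowSums(m$TV[, idx, drop = FALSE], na.rm = TRUE) / ncmp
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  out <- rep(NA_real_, m$n_pairs)
  ok <- ncmp > 0L & !is.na(w1) & w1 > 0 & w2 > 0
  out[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  out
}

.stat_names <- c("dN", "dS", "d_k2p")

pair_values <- function(x, statistic) {
  if (statistic == "d_k2p") {
    m <- k2p_pair_matrices(x)
    k2p_pair_stat(m, seq_len(x$length))
  } else {
    m <- ng_pair_matrices(x)
    ng_pair_stat(m, seq_len(m$n_codons), statistic)
  }
}

#' Mean pairwise substitution distance over an allele set
#'
#' Computes the chosen statistic for every unordered pair of sequences and
#' returns the arithmetic mean. Pairs raising saturation or no-data are
#' excluded; the number excluded is recorded in the `"excluded_pairs"`
#' attribute.
#'
#' @param x An [allele_set()] with at least 2 sequences.
#' @param statistic `"dN"`, `"dS"` (Nei-Gojobori proportions with
#'   Jukes-Cantor correction) or `"d_k2p"` (Kimura 2-parameter).
#' @return The mean pairwise distance, with attributes `n_pairs` and
#'   `excluded_pairs`.
#' @export
mean_pairwise <- function(x, statistic = c("dN", "dS", "d_k2p")) {
  statistic <- match.arg(statistic)
  vals <- pair_values(x, statistic)
  if (all(is.na(vals)))
    cond_error("pbrselect_nodata", "all sequence pairs excluded")
  structure(mean(vals, na.rm = TRUE),
            n_pairs = length(vals), excluded_pairs = sum(is.na(vals)))
}

#' Codon-bootstrap standard error of a mean pairwise distance
#'
#' The resampling unit is the codon column for `dN`/`dS` and the nucleotide
#' column for `d_k2p`. Each replicate redraws columns with replacement to
#' the original length and recomputes the mean pairwise statistic; the
#' standard error is the standard deviation across replicates (divisor
#' `replicates - 1`). Replicate streams are derived from the master seed by
#' replicate index, so results are reproducible for a fixed seed.
#'
#' @inheritParams mean_pairwise
#' @param replicates Number of bootstrap replicates (>= 2).
#' @param seed Integer master seed.
#' @return Object of class `substitution_estimate` with fields `estimate`,
#'   `std_error`, `replicates`, `seed`, `statistic`.
#' @export
bootstrap_se <- function(x, statistic = c("dN", "dS", "d_k2p"),
                         replicates = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  if (statistic == "d_k2p") {
    m <- k2p_pair_matrices(x)
    L <- x$length
    stat_fun <- function(idx) k2p_pair_stat(m, idx)
  } else {
    m <- ng_pair_matrices(x)
    L <- m$n_codons
    stat_fun <- function(idx) ng_pair_stat(m, idx, statistic)
  }
  point_pairs <- stat_fun(seq_len(L))
  if (all(is.na(point_pairs)))
    cond_error("pbrselect_nodata", "all sequence pairs excluded")
  point <- mean(point_pairs, na.rm = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  reps <- vapply(seq_len(replicates), function(r) {
    set.seed(rep_seeds[r])
    idx <- sample.int(L, L, replace = TRUE)
    v <- stat_fun(idx)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  dropped <- sum(is.na(reps))
  se <- stats::sd(reps, na.rm = TRUE)
  structure(list(estimate = point, std_error = se, replicates = replicates,
                 seed = seed, statistic = statistic,
                 dropped_replicates = dropped),
            class = "substitution_estimate")
}

#' @export
print.substitution_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (SE %.4f; %d bootstrap replicates, seed %d)\n",
              x$statistic, x$estimate, x$std_error, x$replicates, x$seed))
  invisible(x)
}

#' One-tailed Z-test of positive selection
#'
#' Tests the alternative dN > dS (positive/balancing selection) with
#' `Z = (dN - dS) / sqrt(SE_dN^2 + SE_dS^2)` and the one-tailed upper
#' standard-normal probability. Bootstrap variances of the two estimates
#' are treated as independent.
#'
#' @param dn,ds `substitution_estimate` objects for dN and dS from the same
#'   alignment and partition stratum.
#' @return Object of class `selection_test` with fields `dn`, `ds`,
#'   `ratio` (`NA` when dS = 0), `z_stat`, `p_value`.
#' @export
z_test_selection <- function(dn, ds) {
  stopifnot(inherits(dn, "substitution_estimate"),
            inherits(ds, "substitution_estimate"))
  denom <- sqrt(dn$std_error^2 + ds$std_error^2)
  delta <- dn$estimate - ds$estimate
  if (denom == 0) {
    if (delta == 0) {
      z <- 0
    } else {
      cond_error("pbrselect_degenerate_variance",
                 "zero bootstrap variance with unequal dN, dS")
    }
  } else z <- delta / denom
  ratio <- if (ds$estimate > 0) dn$estimate / ds$estimate else NA_real_
  structure(list(dn = dn, ds = ds, ratio = ratio,
                 ratio_defined = ds$estimate > 0,
                 z_stat = z,
                 p_value = stats::pnorm(z, lower.tail = FALSE)),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf("dN = %.3f (%.3f)   dS = %.3f (%.3f)\n",
              x$dn$estimate, x$dn$std_error, x$ds$estimate, x$ds$std_error))
  cat(sprintf("dN/dS = %s   Z = %.3f   one-tailed P(dN > dS) = %.3f\n",
              if (x$ratio_defined) sprintf("%.2f", x$ratio) else "undef",
              x$z_stat, x$p_value))
  invisible(x)
}

#' Fit a codon-partitioned Nei-Gojobori selection analysis
#'
#' The central estimator of the package: for each stratum of the codon
#' partition (PBR, non-PBR, and all codons) it computes the mean pairwise
#' Kimura 2-parameter nucleotide distance, the mean pairwise Jukes-Cantor
#' corrected nonsynonymous (dN) and synonymous (dS) Nei-Gojobori distances
#' with codon-bootstrap standard errors, the dN/dS ratio, and the one-tailed
#' Z-test of positive selection.
#'
#' @param x An [allele_set()] (deduplicate first with
#'   [dedupe_identical()] if the panel may contain identical alleles).
#' @param partition A [codon_partition()], or `NULL` to analyze all codons
#'   as a single stratum.
#' @param replicates Bootstrap replicates for standard errors (default 1000).
#' @param seed Integer master seed for all bootstrap draws.
#' @return Object of class `ng_selection`; see [print.ng_selection()],
#'   [summary.ng_selection()], [coef.ng_selection()].
#' @examples
#' panel <- make_fixture_panel("tiny")
#' fit <- ng_selection(panel$alleles, panel$partition,
#'                     replicates = 100, seed = 1)
#' fit
#' @export
ng_selection <- function(x, partition = NULL, replicates = 1000L,
                         seed = 1L) {
  stopifnot(inherits(x, "allele_set"))
  ncod <- x$length %/% 3L
  strata <- if (is.null(partition)) {
    list(All = seq_len(ncod))
  } else {
    stopifnot(inherits(partition, "codon_partition"))
    if (partition$total != ncod)
      stop("partition covers ", partition$total,
           " codons but alignment has ", ncod, call. = FALSE)
    list(PBR = partition$pbr, `Non-PBR` = nonpbr_indices(partition),
         All = seq_len(ncod))
  }
  res <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    if (length(idx) == 0L) return(NULL)
    sub <- subset_codons(x, idx)
    dn <- bootstrap_se(sub, "dN", replicates, seed)
    ds <- bootstrap_se(sub, "dS", replicates, seed)
    k2p <- bootstrap_se(sub, "d_k2p", replicates, seed)
    list(name = nm, n_codons = length(idx), k2p = k2p,
         test = z_test_selection(dn, ds))
  })
  names(res) <- names(strata)
  res <- Filter(Negate(is.null), res)
  structure(list(call = match.call(), label = x$label,
                 n_alleles = length(x$ids), partition = partition,
                 replicates = replicates, seed = seed, strata = res),
            class = "ng_selection")
}

# numeric per-stratum summary used by coef/print/report
ng_selection_table <- function(object) {
  rows <- lapply(object$strata, function(s) {
    data.frame(stratum = s$name, n_codons = s$n_codons,
               d_k2p = s$k2p$estimate, d_k2p_se = s$k2p$std_error,
               dN = s$test$dn$estimate, dN_se = s$test$dn$std_error,
               dS = s$test$ds$estimate, dS_se = s$test$ds$std_error,
               dN_dS = s$test$ratio, z = s$test$z_stat,
               p = s$test$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ng_selection <- function(x, digits = 3, ...) {
  cat("Codon-partitioned Nei-Gojobori selection analysis\n")
  if (nzchar(x$label)) cat("Panel:", x$label, "\n")
  cat(x$n_alleles, "alleles;", x$replicates,
      "bootstrap replicates (seed", paste0(x$seed, ")"), "\n\n")
  tab <- ng_selection_table(x)
  disp <- data.frame(
    Positions = tab$stratum, N = tab$n_codons,
    `d(K2P)` = sprintf("%.3f(%.3f)", tab$d_k2p, tab$d_k2p_se),
    `dN(SE)` = sprintf("%.3f(%.3f)", tab$dN, tab$dN_se),
    `dS(SE)` = sprintf("%.3f(%.3f)", tab$dS, tab$dS_se),
    `dN/dS` = ifelse(is.na(tab$dN_dS), "undef",
                     sprintf("%.2f", tab$dN_dS)),
    P = sprintf("%.3f", pmin(tab$p, 1)),
    check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Coefficients of a selection fit
#' @param object An `ng_selection` fit.
#' @param ... Ignored.
#' @return Numeric matrix, one row per stratum: d(K2P), dN, dS, dN/dS, Z, P.
#' @export
coef.ng_selection <- function(object, ...) {
  tab <- ng_selection_table(object)
  m <- as.matrix(tab[, c("d_k2p", "dN", "dS", "dN_dS", "z", "p")])
  rownames(m) <- tab$stratum
  m
}

#' @export
as.data.frame.ng_selection <- function(x, ...) ng_selection_table(x)

#' Summarize a selection fit
#' @param object An `ng_selection` fit.
#' @param ... Ignored.
#' @return Object of class `summary.ng_selection`: the per-stratum table
#'   plus significance calls at the 5 percent level.
#' @export
summary.ng_selection <- function(object, ...) {
  tab <- ng_selection_table(object)
  tab$significant_5pct <- tab$p < 0.05
  structure(list(label = object$label, n_alleles = object$n_alleles,
                 replicates = object$replicates, seed = object$seed,
                 table = tab),
            class = "summary.ng_selection")
}

#' @export
print.summary.ng_selection <- function(x, ...) {
  cat("Z-test of positive selection (alternative dN > dS), one-tailed\n")
  if (nzchar(x$label)) cat("Panel:", x$label, "\n")
  cat(x$n_alleles, "alleles;", x$replicates, "bootstrap replicates\n\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot dN and dS per partition stratum
#'
#' Side-by-side bars of dN and dS per stratum with +/- 1 SE whiskers; the
#' visual signature of positive selection is dN exceeding dS in the PBR bar
#' pair only.
#'
#' @param x An `ng_selection` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ng_selection <- function(x, ...) {
  tab <- ng_selection_table(x)
  h <- rbind(dN = tab$dN, dS = tab$dS)
  se <- rbind(tab$dN_se, tab$dS_se)
  bp <- graphics::barplot(h, beside = TRUE, names.arg = tab$stratum,
                          legend.text = c("dN", "dS"),
                          ylab = "substitutions per site",
                          ylim = c(0, max(h + se) * 1.15), ...)
  ok <- se > 0
  if (any(ok))
    graphics::arrows(bp[ok], h[ok], bp[ok], (h + se)[ok], angle = 90,
                     length = 0.04)
  invisible(bp)
}
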