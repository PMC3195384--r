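# Nei-Gojobori (1986) codon machinery.
#
# All counting is driven by lookup tables built once per session: the 64
# codons in fixed lexicographic order (A<C<G<T), their amino acids under the
# standard genetic code, per-codon expected synonymous site fractions, and
# the 61x61 pathway-averaged synonymous/nonsynonymous difference tables.

.pbr_env <- new.env(parent = emptyenv())

.bases <- c("A", "C", "G", "T")

ng_tables <- function() {
  if (!is.null(.pbr_env$tables)) return(.pbr_env$tables)
  codons <- as.vector(outer(outer(.bases, .bases, paste0), .bases, paste0))
  codons <- sort(codons)  # AAA, AAC, ..., TTT
  aa <- vapply(codons, function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
               "", USE.NAMES = FALSE)
  names(aa) <- codons
  sense <- codons[aa != "*"]

  # expected synonymous sites per sense codon: for each position, the
  # fraction of the 3 single-base changes preserving the amino acid; changes
  # to stop codons count as nonsynonymous (classic NG86 convention)
  syn_sites <- rep(NA_real_, 64L)
  names(syn_sites) <- codons
  for (cd in sense) {
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(.bases, ch[pos])) {
        mut <- ch; mut[pos] <- b
        if (aa[paste(mut, collapse = "")] == aa[cd]) s <- s + 1 / 3
      }
    }
    syn_sites[cd] <- s
  }

  # pathway-averaged differences between every ordered pair of sense codons
  idx <- function(cd) match(cd, codons)
  SD <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  ND <- SD
  for (a in sense) SD[a, a] <- ND[a, a] <- 0
  pair_diff <- function(a, b) {
    pa <- strsplit(a, "")[[1]]; pb <- strsplit(b, "")[[1]]
    dif <- which(pa != pb)
    k <- length(dif)
    if (k == 0L) return(c(0, 0))
    perms <- switch(k, list(dif),
                    list(dif, dif[c(2, 1)]),
                    list(dif[c(1, 2, 3)], dif[c(1, 3, 2)], dif[c(2, 1, 3)],
                         dif[c(2, 3, 1)], dif[c(3, 1, 2)], dif[c(3, 2, 1)]))
    score <- function(ord) {
      cur <- pa; s <- 0; n <- 0; ok <- TRUE
      for (pos in ord) {
        prev_aa <- aa[paste(cur, collapse = "")]
        cur[pos] <- pb[pos]
        nxt <- paste(cur, collapse = "")
        if (aa[nxt] == "*" && nxt != b) ok <- FALSE  # stop intermediate
        if (aa[nxt] == prev_aa) s <- s + 1 else n <- n + 1
      }
      c(s, n, ok)
    }
    sc <- vapply(perms, score, numeric(3))
    keep <- sc[3, ] == 1
    if (!any(keep)) keep <- rep(TRUE, ncol(sc))  # all stop-crossing: use all
    c(mean(sc[1, keep]), mean(sc[2, keep]))
  }
  for (a in sense) for (b in sense) {
    if (a < b) {
      d <- pair_diff(a, b)
      SD[a, b] <- SD[b, a] <- d[1]
      ND[a, b] <- ND[b, a] <- d[2]
    }
  }

  .pbr_env$tables <- list(codons = codons, aa = aa, sense = sense,
                          syn_sites = syn_sites, SD = SD, ND = ND)
  .pbr_env$tables
}

# vectorized codon -> amino acid; codons with gaps/N (any non-ACGT) give "X"
translate_codons <- function(cods) {
  tb <- ng_tables()
  out <- unname(tb$aa[cods])
  out[is.na(out)] <- "X"
  out
}

# vectorized codon -> row index into the 64-codon tables; NA for non-sense
codon_codes <- function(cods) {
  tb <- ng_tables()
  i <- match(cods, tb$codons)
  i[!is.na(i) & tb$aa[i] == "*"] <- NA_integer_
  i
}

split_into_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

cond_error <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Expected synonymous and nonsynonymous sites of a codon
#'
#' Nei-Gojobori site counting: for each of the three codon positions the
#' synonymous fraction is the number of the 3 possible single-base changes
#' that preserve the amino acid, divided by 3, summed over positions.
#' Changes creating stop codons count as nonsynonymous, so
#' `syn_sites + nonsyn_sites == 3` for every sense codon.
#'
#' @param codon A 3-letter sense codon over `A,C,G,T`.
#' @return List with `syn_sites` and `nonsyn_sites` (fractional).
#' @examples
#' codon_site_counts("TTT")  # 1/3 synonymous sites
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  tb <- ng_tables()
  if (!codon %in% tb$sense)
    cond_error("pbrselect_undefined_codon",
               paste0("not a sense codon: ", codon))
  s <- unname(tb$syn_sites[codon])
  list(syn_sites = s, nonsyn_sites = 3 - s)
}

#' Pathway-averaged substitution differences between two codons
#'
#' When the codons differ at k positions, all k! orderings of single-base
#' steps are enumerated; orderings passing through a stop codon are
#' discarded (unless every ordering does, in which case all are used), each
#' step is classified synonymous/nonsynonymous against the standard code,
#' and the unweighted mean counts over admissible pathways are returned.
#'
#' @param codon_a,codon_b 3-letter sense codons.
#' @return List with `syn_diffs`, `nonsyn_diffs` and `compared_codons` (1).
#' @examples
#' pathway_differences("TTT", "GTA")  # 0.5 synonymous, 1.5 nonsynonymous
#' @export
pathway_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  tb <- ng_tables()
  if (!codon_a %in% tb$sense || !codon_b %in% tb$sense)
    cond_error("pbrselect_undefined_codon",
               paste0("not sense codons: ", codon_a, ", ", codon_b))
  list(syn_diffs = unname(tb$SD[codon_a, codon_b]),
       nonsyn_diffs = unname(tb$ND[codon_a, codon_b]),
       compared_codons = 1L)
}

#' Proportions of synonymous and nonsynonymous differences between two
#' aligned coding sequences
#'
#' Codon sites containing a gap, `N`, or a stop codon in either sequence are
#' excluded pairwise. Site totals `N` and `S` are the means of the two
#' sequences' summed per-codon site counts over the included codons;
#' `pN = sum(nonsyn_diffs) / N`, `pS = sum(syn_diffs) / S`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length, a multiple
#'   of 3.
#' @return List with `pN`, `pS`, `N`, `S`, `Nd`, `Sd`, `compared_codons`.
#' @export
pairwise_pn_ps <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b) || nchar(seq_a) %% 3L != 0L)
    stop("sequences must have equal length, a multiple of 3", call. = FALSE)
  tb <- ng_tables()
  ia <- codon_codes(split_into_codons(seq_a))
  ib <- codon_codes(split_into_codons(seq_b))
  use <- !is.na(ia) & !is.na(ib)
  if (!any(use))
    cond_error("pbrselect_nodata", "no usable codon sites in pair")
  ia <- ia[use]; ib <- ib[use]
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * sum(use) - S
  Sd <- sum(tb$SD[cbind(ia, ib)])
  Nd <- sum(tb$ND[cbind(ia, ib)])
  list(pN = if (N > 0) Nd / N else 0, pS = if (S > 0) Sd / S else 0,
       N = N, S = S, Nd = Nd, Sd = Sd, compared_codons = sum(use))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`, defined for `0 <= p < 3/4`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance in substitutions per site.
#' @export
jukes_cantor_correct <- function(p) {
  if (any(p < 0) || any(p >= 0.75))
    cond_error("pbrselect_saturation",
               "proportion outside [0, 3/4): Jukes-Cantor distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}

# NA-returning variant used in bootstrap loops
jc_or_na <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

.purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

#' Kimura 2-parameter nucleotide distance
#'
#' Columns where either sequence has a gap or ambiguous base are deleted
#' pairwise. With transition proportion `P` and transversion proportion `Q`
#' over the comparable sites, `d = -(1/2) log((1 - 2P - Q) sqrt(1 - 2Q))`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must have equal length", call. = FALSE)
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  use <- a %in% .bases & b %in% .bases
  if (!any(use))
    cond_error("pbrselect_nodata", "no comparable nucleotide sites")
  a <- a[use]; b <- b[use]
  diff <- a != b
  ts <- diff & (.purine[a] == .purine[b])
  P <- mean(ts); Q <- mean(diff & !ts)
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    cond_error("pbrselect_saturation", "K2P distance undefined (saturation)")
  -0.5 * log(w1 * sqrt(w2))
}

#' Poisson-corrected amino-acid distance
#'
#' With `p` the fraction of differing residues, `d = -log(1 - p)`.
#'
#' @param res_a,res_b Amino-acid strings of equal nonzero length.
#' @return Distance in substitutions per site.
#' @export
poisson_distance <- function(res_a, res_b) {
  if (nchar(res_a) != nchar(res_b) || nchar(res_a) == 0L)
    stop("residue strings must have equal nonzero length", call. = FALSE)
  a <- strsplit(res_a, "")[[1]]; b <- strsplit(res_b, "")[[1]]
  p <- mean(a != b)
  if (p >= 1)
    cond_error("pbrselect_saturation",
               "Poisson distance undefined (all residues differ)")
  -log(1 - p)
}
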