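# Poisson-corrected amino-acid distances, Neighbor-Joining with a
# deterministic lexicographic tie-break, bootstrap supports, newick I/O.
# Trees are ape "phylo" objects; the sum of branch lengths is attached as
# attribute "total_length".

#' Remove alignment columns with any gap or missing residue
#'
#' Complete-deletion filtering: every column containing `X` or `-` in ANY
#' sequence is removed from all sequences. The retained 1-based column
#' indices are recorded in the `"kept_columns"` attribute.
#'
#' @param residues Named character vector of equal-length amino-acid strings.
#' @return Filtered residue strings (names preserved).
#' @export
complete_deletion <- function(residues) {
  if (inherits(residues, "allele_set"))
    residues <- translate_alleles(residues)
  m <- seq_char_matrix(residues)
  keep <- which(colSums(matrix(m %in% .missing_aa, nrow(m))) == 0L)
  if (length(keep) == 0L)
    cond_error("pbrselect_nodata",
               "complete deletion removed every column")
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(residues)
  attr(out, "kept_columns") <- keep
  out
}

#' Poisson-corrected distance matrix over amino-acid sequences
#'
#' @param residues Named character vector of equal-length amino-acid strings
#'   (apply [complete_deletion()] first to reproduce the standard workflow).
#' @return Symmetric numeric matrix with zero diagonal, labelled by names.
#' @export
poisson_dist_matrix <- function(residues) {
  if (inherits(residues, "allele_set"))
    residues <- translate_alleles(residues)
  n <- length(residues)
  labs <- names(residues)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(poisson_distance(residues[[i]], residues[[j]]),
                  pbrselect_saturation = function(e)
                    cond_error("pbrselect_saturation",
                               paste0("saturated pair: ", labs[i], " / ",
                                      labs[j])))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined, with ties broken by the lexicographically smallest
#' pair of cluster labels (a cluster is labelled by its smallest member
#' taxon), so the result is independent of input row order. Negative branch
#' lengths are clamped to zero; the total clamped deficit is recorded in the
#' `"clamped"` attribute.
#'
#' @param D Symmetric nonnegative matrix with zero diagonal and taxon
#'   dimnames; at least 3 taxa.
#' @return An unrooted `phylo` object (basal trifurcation) with attribute
#'   `"total_length"`, the sum of branch lengths.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix", call. = FALSE)
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(D < 0) || any(abs(D - t(D)) > 1e-8) || any(abs(diag(D)) > 1e-12))
    stop("D must be symmetric and nonnegative with zero diagonal",
         call. = FALSE)
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(D)))
  if (any(grepl("[(),:;]", labs)))
    stop("taxon labels may not contain newick metacharacters", call. = FALSE)
  nwk <- labs           # newick fragment per active cluster
  rep_lab <- labs       # smallest member label, used for tie-breaking
  d <- D
  clamped <- 0
  fmt <- function(x) sprintf("%.10g", x)
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(rep_lab[cand[k, 1]], rep_lab[cand[k, 2]]))
      paste(pr, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":",
                      fmt(lj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                   c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    d <- d_new
  }
  # final trifurcation
  a <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  b <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  cc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- paste0("(", nwk[1], ":", fmt(a), ",", nwk[2], ":", fmt(b), ",",
                nwk[3], ":", fmt(cc), ");")
  tr <- ape::read.tree(text = txt)
  attr(tr, "total_length") <- sum(tr$edge.length)
  attr(tr, "clamped") <- clamped
  tr
}

# canonical signatures of the nontrivial bipartitions of an unrooted tree:
# each internal node (except the basal one) splits the leaves in two; the
# side NOT containing the reference (first sorted) label is the signature
tree_bipartitions <- function(tr) {
  parts <- ape::prop.part(tr)
  ref <- sort(tr$tip.label)[1L]
  all_tips <- tr$tip.label
  sig <- vapply(parts[-1L], function(ix) {   # parts[[1]] is the root = all
    side <- all_tips[ix]
    if (ref %in% side) side <- setdiff(all_tips, side)
    paste(sort(side), collapse = "\r")
  }, "")
  # drop trivial splits (single tip / all-but-one)
  sizes <- lengths(strsplit(sig, "\r", fixed = TRUE))
  sig[sizes >= 2L & sizes <= length(all_tips) - 2L]
}

#' Bootstrap supports for a Neighbor-Joining amino-acid tree
#'
#' Builds the point-estimate tree from the given residues (Poisson
#' distances, NJ), then resamples residue columns with replacement
#' `replicates` times, rebuilds the tree each time, and annotates every
#' internal edge of the point tree with the percentage of replicates whose
#' tree contains the same leaf bipartition. Deterministic for a fixed seed.
#'
#' @param residues Named character vector of equal-length amino-acid strings
#'   (already complete-deletion filtered in the standard workflow).
#' @param replicates Bootstrap replicates (>= 1), default 1000.
#' @param seed Integer master seed.
#' @return The point `phylo` tree with `node.label` holding supports (root
#'   label empty) and attributes `total_length` and `supports`.
#' @export
bootstrap_supports <- function(residues, replicates = 1000L, seed = 1L) {
  if (inherits(residues, "allele_set"))
    residues <- translate_alleles(residues)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  L <- nchar(residues[[1L]])
  point <- nj_tree(poisson_dist_matrix(residues))
  point_sig <- tree_bipartitions(point)
  counts <- setNames(numeric(length(point_sig)), point_sig)
  chars <- seq_char_matrix(residues)
  labs <- names(residues)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  n_ok <- 0L
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    idx <- sample.int(L, L, replace = TRUE)
    res_r <- apply(chars[, idx, drop = FALSE], 1L, paste, collapse = "")
    names(res_r) <- labs
    tr_r <- tryCatch(nj_tree(poisson_dist_matrix(res_r)),
                     pbrselect_saturation = function(e) NULL)
    if (is.null(tr_r)) next   # saturated replicate: no tree to score
    n_ok <- n_ok + 1L
    sig_r <- tree_bipartitions(tr_r)
    hit <- point_sig %in% sig_r
    counts[hit] <- counts[hit] + 1
  }
  if (n_ok == 0L && length(counts))
    cond_error("pbrselect_nodata", "every bootstrap replicate saturated")
  supp <- if (n_ok > 0L) 100 * counts / n_ok else counts
  # map supports onto internal nodes: recompute each node's signature
  parts <- ape::prop.part(point)
  ref <- sort(point$tip.label)[1L]
  node_lab <- character(point$Nnode)
  for (k in seq_along(parts)) {
    side <- point$tip.label[parts[[k]]]
    if (ref %in% side) side <- setdiff(point$tip.label, side)
    s <- paste(sort(side), collapse = "\r")
    if (s %in% names(supp))
      node_lab[k] <- sprintf("%g", round(supp[[s]], 1))
  }
  point$node.label <- node_lab
  attr(point, "supports") <- supp
  attr(point, "total_length") <- sum(point$edge.length)
  point
}

#' Write a tree as newick
#'
#' Branch lengths rounded to 6 decimals; bootstrap supports (when present)
#' written as internal-node labels. Re-reading with [read_newick()]
#' reproduces topology, lengths and supports.
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a newick tree
#' @param path Path to a newick file.
#' @return A `phylo` object with attribute `"total_length"`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  attr(tr, "total_length") <- sum(tr$edge.length)
  tr
}
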