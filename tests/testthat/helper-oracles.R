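# Independent brute-force oracles used to check the fast lookup-table
# implementation. These deliberately re-derive everything from the genetic
# code by direct enumeration and share no code with the package internals.

.ora_bases <- c("A", "C", "G", "T")

ora_translate <- function(chars) seqinr::translate(chars)

# synonymous site fraction of a codon by enumerating its 9 mutants
oracle_site_counts <- function(codon) {
  ch0 <- strsplit(codon, "")[[1]]
  aa0 <- ora_translate(ch0)
  s <- 0
  for (pos in 1:3) {
    for (b in .ora_bases) {
      if (b == ch0[pos]) next
      ch <- ch0
      ch[pos] <- b
      if (ora_translate(ch) == aa0) s <- s + 1 / 3
    }
  }
  s
}

ora_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(ora_perms(v[-i]), function(p) c(v[i], p))))
}

# pathway-averaged syn/nonsyn differences by explicit enumeration of all
# orderings of the differing positions, stop-free pathways preferred
oracle_pathway <- function(codon_a, codon_b) {
  pa <- strsplit(codon_a, "")[[1]]
  pb <- strsplit(codon_b, "")[[1]]
  dif <- which(pa != pb)
  if (length(dif) == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- lapply(ora_perms(dif), function(ord) {
    cur <- pa
    s <- 0; n <- 0; stop_free <- TRUE
    for (pos in ord) {
      before <- ora_translate(cur)
      cur[pos] <- pb[pos]
      after <- ora_translate(cur)
      if (after == "*") stop_free <- FALSE
      if (after == before) s <- s + 1 else n <- n + 1
    }
    list(s = s, n = n, stop_free = stop_free)
  })
  ok <- vapply(paths, `[[`, TRUE, "stop_free")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(syn = mean(vapply(paths[ok], `[[`, 0, "s")),
    nonsyn = mean(vapply(paths[ok], `[[`, 0, "n")))
}

# all 61 sense codons, derived independently of the package tables
sense_codons <- local({
  all64 <- as.vector(outer(outer(.ora_bases, .ora_bases, paste0),
                           .ora_bases, paste0))
  all64[vapply(all64, function(cd)
    ora_translate(strsplit(cd, "")[[1]]) != "*", TRUE)]
})

random_sense_sequence <- function(n_codons) {
  paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
}

# random unrooted binary tree with known branch lengths and its additive
# distance matrix (path lengths between leaves)
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.2, 1.5))
  D <- ape::cophenetic.phylo(tr)
  labs <- sort(tr$tip.label)
  list(tree = tr, D = D[labs, labs])
}

tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
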