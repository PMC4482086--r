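# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force or closed form,
# never by calling the code paths they check.

random_seq <- function(n, gc = 50) {
  g <- gc / 100
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)),
        collapse = "")
}

# Plant a direct-repeat pair: copy a core_len-mer from pos1 to pos2 with
# mismatches at the given core positions (1-based within the core).
plant_repeat <- function(seq, pos1, pos2, core_len = 21, mm_at = integer(0)) {
  core <- substr(seq, pos1, pos1 + core_len - 1L)
  ch <- strsplit(core, "")[[1]]
  for (p in mm_at)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  substr(seq, pos2, pos2 + core_len - 1L) <- paste(ch, collapse = "")
  seq
}

# Exhaustive all-pairs Hamming oracle for direct repeats: for every
# diagonal (pair spacing) with any window pair at or under the mismatch
# cap, the minimum mismatch count and the positions attaining it.
oracle_direct_repeats <- function(seq, core_len = 21, max_mm = 3) {
  ch <- strsplit(seq, "")[[1]]
  N <- length(ch)
  out <- list()
  for (d in core_len:(N - core_len)) {
    neq <- ch[1:(N - d)] != ch[(1 + d):N]
    if (length(neq) < core_len) next
    cs <- cumsum(c(0L, neq))
    wins <- cs[(core_len + 1L):length(cs)] - cs[1:(length(cs) - core_len)]
    best <- min(wins)
    if (best <= max_mm)
      out[[as.character(d)]] <- list(diag = d, mm = best,
                                     starts = which(wins == best))
  }
  out
}

# Least-squares quartet oracle: fits branch lengths for each of the three
# unrooted 4-taxon topologies by ordinary least squares and returns the
# split of the minimum-SSE topology as a sorted label pair.
ls_quartet_split <- function(d) {
  labs <- rownames(d)
  stopifnot(length(labs) == 4L)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  sse <- vapply(splits, function(s) {
    grp1 <- s; grp2 <- setdiff(1:4, s)
    # path-length design over edges (e1..e4 pendant, e5 internal)
    pairs <- utils::combn(4, 2)
    X <- t(apply(pairs, 2, function(pr) {
      row <- numeric(5)
      row[pr] <- 1
      same <- (all(pr %in% grp1)) || (all(pr %in% grp2))
      if (!same) row[5] <- 1
      row
    }))
    y <- apply(pairs, 2, function(pr) d[pr[1], pr[2]])
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, 0)
  best <- labs[splits[[which.min(sse)]]]
  ref <- min(labs)
  if (ref %in% best) sort(best) else sort(setdiff(labs, best))
}

# The split containing taxon 1 in an unrooted 4-taxon phylo tree.
quartet_split_of_tree <- function(tree) {
  tr <- ape::unroot(tree)
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  bip <- Filter(function(p) length(p) == 2L, parts)
  if (!length(bip)) {
    # derive the cherry containing taxon 1 from the edge structure
    # (prop.part on unrooted trees always yields one 2-taxon clade here)
    stop("no quartet split found")
  }
  s <- labs[bip[[1]]]
  if (!(min(labs) %in% s)) s <- setdiff(labs, s)
  sort(s)
}

# Brute-force reciprocal-best-hit orthology: explicit loops + union-find,
# sharing only the raw scoring function with the implementation.
oracle_rbh <- function(proteomes, ratio_threshold = 0.2, score_floor = 50) {
  tab <- do.call(rbind, lapply(names(proteomes), function(isl) {
    p <- proteomes[[isl]]
    if (!length(p)) return(NULL)
    data.frame(island = isl, gene = names(p), seq = unname(p),
               uid = paste(isl, names(p), sep = ":"),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(tab)
  score <- function(a, b) dusaGEI:::local_scores(tab$seq[a], tab$seq[b])
  selfs <- vapply(seq_len(n), function(i) score(i, i), 0)
  best_to <- function(i, isl) {
    idx <- which(tab$island == isl)
    sc <- vapply(idx, function(j) score(i, j), 0)
    idx[which.max(sc)]
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (isl in setdiff(unique(tab$island), tab$island[i])) {
      if (!any(tab$island == isl)) next
      j <- best_to(i, isl)
      if (best_to(j, tab$island[i]) != i) next
      s <- score(i, j)
      if (s < score_floor || s / max(selfs[i], selfs[j]) < ratio_threshold)
        next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  clusters <- split(seq_len(n), roots)
  islands_per <- vapply(clusters, function(ix) length(unique(tab$island[ix])), 0L)
  genes_per <- vapply(clusters, length, 0L)
  list(n_genes_total = n,
       n_unique = sum(genes_per[islands_per == 1L]),
       n_clusters = length(clusters),
       n_core = sum(islands_per == length(proteomes)),
       membership = lapply(clusters, function(ix) sort(tab$uid[ix])))
}

# Reverse-complement an entire annotated replicon (sequence + features).
revcomp_annotation <- function(rep, features) {
  N <- rep$length
  f <- features
  new_start <- N - f$end + 1L
  new_end <- N - f$start + 1L
  f$start <- new_start; f$end <- new_end
  f$strand <- ifelse(f$strand == "+", "-", "+")
  list(replicon = replicon(rep$id, revcomp(rep$seq), rep$topology),
       features = f)
}
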