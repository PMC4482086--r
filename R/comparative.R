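#' Pairwise identity and similarity matrices
#'
#' Global affine-gap alignment (BLOSUM62, open 11 / extend 1) of every pair
#' of proteins. Identity is 100 x matches / alignment columns; similarity
#' additionally counts positive-score substitutions. Columns belonging to a
#' terminal gap run in either sequence are excluded from the denominator
#' (one of the common matrix-program conventions; configurable).
#'
#' @param proteins Named character vector of amino-acid sequences (>= 2).
#' @param exclude_terminal_gaps Drop terminal-gap columns from the
#'   denominator.
#' @return Object of class `gei_distmat` with `labels`, `identity`,
#'   `similarity` (percent matrices) and `distance` (1 - identity/100).
#' @export
identity_matrix <- function(proteins, exclude_terminal_gaps = TRUE) {
  if (length(proteins) < 2L) stop("at least two sequences are required")
  proteins <- vapply(proteins, check_protein, "", what = "sequence")
  if (is.null(names(proteins)) || any(!nzchar(names(proteins))))
    names(proteins) <- sprintf("seq%d", seq_along(proteins))
  n <- length(proteins)
  labels <- names(proteins)
  idm <- matrix(100, n, n, dimnames = list(labels, labels))
  sim <- matrix(100, n, n, dimnames = list(labels, labels))
  B <- blosum62()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(proteins[i], proteins[j])
      x <- strsplit(al$a, "")[[1]]
      y <- strsplit(al$b, "")[[1]]
      keep <- rep(TRUE, length(x))
      if (exclude_terminal_gaps) {
        for (v in list(x, y)) {
          ng <- which(v != "-")
          keep[seq_along(v) < min(ng)] <- FALSE
          keep[seq_along(v) > max(ng)] <- FALSE
        }
      }
      x <- x[keep]; y <- y[keep]
      ncols <- length(x)
      match_n <- sum(x == y & x != "-")
      both <- x != "-" & y != "-"
      pos_n <- sum(vapply(which(both), function(k) B[x[k], y[k]] > 0, TRUE))
      idm[i, j] <- idm[j, i] <- 100 * match_n / ncols
      sim[i, j] <- sim[j, i] <- 100 * pos_n / ncols  # positives include identities
    }
  }
  structure(list(labels = labels, identity = idm, similarity = sim,
                 distance = 1 - idm / 100),
            class = "gei_distmat")
}

#' @export
print.gei_distmat <- function(x, ...) {
  cat(sprintf("<identity/similarity matrices> %d sequences\n",
              length(x$labels)))
  print(round(x$identity, 1))
  invisible(x)
}

as_dist_matrix <- function(dm) {
  if (inherits(dm, "gei_distmat")) return(dm$distance)
  if (inherits(dm, "dist")) return(as.matrix(dm))
  if (is.matrix(dm)) return(dm)
  stop("expected a gei_distmat, dist or matrix")
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining on a distance matrix. Input labels are
#' sorted lexicographically before agglomeration so tied joins resolve
#' deterministically; negative branch-length estimates are clamped to zero
#' and flagged via the `clamped` attribute.
#'
#' @param dm A `gei_distmat`, `dist` or symmetric numeric matrix.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  d <- as_dist_matrix(dm)
  if (nrow(d) < 3L) stop("neighbour joining requires at least 3 labels")
  if (any(!is.finite(d))) stop("non-finite distances")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

p_distance <- function(mat) {
  # proportion of differing columns among columns where both rows are
  # residues (gaps and X ignored pairwise)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else NA
    }
  }
  d
}

#' Neighbour-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, recomputes a p-distance
#' NJ tree per replicate, and reports per-internal-edge support as the
#' fraction of replicates containing the corresponding bipartition.
#' Seeded and exactly reproducible.
#'
#' @param alignment Named character vector of aligned (equal-length)
#'   amino-acid sequences; `-` marks gaps.
#' @param n_replicates Bootstrap replicates; 0 returns the tree without
#'   support values.
#' @param seed Integer seed.
#' @return A `phylo` tree whose `node.label` holds support fractions in
#'   `[0, 1]` (root label empty); `NULL` node labels when
#'   `n_replicates = 0`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1L) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("alignment sequences must have equal length")
  L <- lens[1]
  if (L < 2L) stop("alignment of 1 column is degenerate")
  if (length(alignment) < 3L) stop("at least 3 sequences are required")
  if (is.null(names(alignment)))
    names(alignment) <- sprintf("seq%d", seq_along(alignment))
  mat <- t(vapply(alignment, function(s) strsplit(s, "")[[1]],
                  character(L)))
  ref <- nj_tree(p_distance(mat))
  if (n_replicates == 0L) return(ref)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boots <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    db <- p_distance(mat[, cols, drop = FALSE])
    if (any(!is.finite(db))) db[!is.finite(db)] <- 1
    boots[[b]] <- nj_tree(db)
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- counts / n_replicates
  ref
}

#' Attachment-site consensus logo
#'
#' Per-column base frequencies and information content for a set of
#' equal-length DNA sequences, as drawn by sequence-logo software: IC =
#' 2 - H - e_n bits, where H is the column Shannon entropy and e_n =
#' 3 / (2 ln2 n) the small-sample correction for n sequences; clamped at 0.
#' Gap characters are excluded per column.
#'
#' @param sequences Character vector of equal-length DNA strings (gaps as
#'   `-`).
#' @param small_sample_correction Apply the e_n correction.
#' @return Data frame with one row per column: `position`, `A`, `C`, `G`,
#'   `T` (frequencies), `n`, `entropy`, `ic`.
#' @export
consensus_logo <- function(sequences, small_sample_correction = TRUE) {
  if (!length(sequences)) stop("at least one sequence is required")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  L <- lens[1]
  mat <- matrix(unlist(strsplit(toupper(sequences), "")),
                nrow = length(sequences), byrow = TRUE)
  out <- lapply(seq_len(L), function(j) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    n <- length(col)
    freqs <- as.numeric(table(factor(col, levels = c("A", "C", "G", "T")))) /
      max(n, 1L)
    p <- freqs[freqs > 0]
    H <- if (n > 0) -sum(p * log2(p)) else NA_real_
    en <- if (small_sample_correction && n > 0) 3 / (2 * log(2) * n) else 0
    ic <- if (n > 0) max(0, 2 - H - en) else NA_real_
    data.frame(position = j, A = freqs[1], C = freqs[2], G = freqs[3],
               T = freqs[4], n = n, entropy = H, ic = ic)
  })
  do.call(rbind, out)
}

#' Reciprocal-best-hit orthology across island proteomes
#'
#' All-vs-all local similarity (BLOSUM62, open 11 / extend 1) between the
#' proteomes of a set of islands. A cross-island gene pair is an orthologue
#' edge iff each gene is the other's best hit in the reciprocal direction
#' and the pair passes the score threshold (score ratio against the larger
#' self-score, plus a raw-score floor - a database-free surrogate for an
#' e-value cutoff). Clusters are connected components of the edge graph
#' plus singletons. Reports the per-gene uniqueness count (genes whose
#' cluster touches exactly one island) and the core clusters (touching all
#' islands).
#'
#' @param island_proteomes Named list; each element a named character
#'   vector of that island's protein sequences.
#' @param ratio_threshold Minimum score / max(self-scores) for an edge.
#' @param score_floor Minimum raw local-alignment score for an edge.
#' @return Object of class `gei_orthology`: `clusters` (list of data
#'   frames with `island`, `gene`), `n_genes_total`, `n_unique`,
#'   `unique_fraction`, `core_clusters` (indices), `edges`.
#' @export
rbh_orthology <- function(island_proteomes, ratio_threshold = 0.2,
                          score_floor = 50) {
  if (length(island_proteomes) < 2L) stop("at least two islands are required")
  if (is.null(names(island_proteomes)))
    names(island_proteomes) <- sprintf("island%d", seq_along(island_proteomes))
  for (i in seq_along(island_proteomes)) {
    p <- island_proteomes[[i]]
    if (length(p) && (is.null(names(p)) || any(!nzchar(names(p)))))
      names(island_proteomes[[i]]) <- sprintf("g%d", seq_along(p))
  }
  islands <- names(island_proteomes)
  gene_tab <- do.call(rbind, lapply(islands, function(isl) {
    p <- island_proteomes[[isl]]
    if (!length(p)) return(NULL)
    data.frame(island = isl, gene = names(p), seq = unname(p),
               uid = paste(isl, names(p), sep = ":"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(gene_tab) || !nrow(gene_tab)) stop("all proteomes are empty")
  selfs <- vapply(gene_tab$seq, self_score, 0)
  names(selfs) <- gene_tab$uid

  # best hit of each gene into each other island
  best_hit <- list()  # best_hit[[uid]][[island]] = list(uid, score)
  for (a in seq_len(nrow(gene_tab))) {
    ga <- gene_tab[a, ]
    for (isl in islands) {
      if (isl == ga$island) next
      tgt <- gene_tab[gene_tab$island == isl, , drop = FALSE]
      if (!nrow(tgt)) next
      sc <- local_scores(ga$seq, tgt$seq)
      k <- which.max(sc)             # ties: first in input order
      best_hit[[ga$uid]][[isl]] <- list(uid = tgt$uid[k], score = sc[k])
    }
  }
  edges <- data.frame(from = character(0), to = character(0),
                      score = numeric(0))
  for (a in seq_len(nrow(gene_tab))) {
    ga <- gene_tab[a, ]
    for (isl in islands) {
      if (isl <= ga$island) next     # each unordered island pair once
      bh <- best_hit[[ga$uid]][[isl]]
      if (is.null(bh)) next
      back <- best_hit[[bh$uid]][[ga$island]]
      if (is.null(back) || back$uid != ga$uid) next
      ratio <- bh$score / max(selfs[ga$uid], selfs[bh$uid])
      if (bh$score < score_floor || ratio < ratio_threshold) next
      edges <- rbind(edges, data.frame(from = ga$uid, to = bh$uid,
                                       score = bh$score))
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(gene_tab$uid)
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  comp <- igraph::components(g)
  member <- comp$membership[gene_tab$uid]
  clusters <- lapply(seq_len(comp$no), function(cid) {
    sel <- gene_tab[member == cid, c("island", "gene"), drop = FALSE]
    rownames(sel) <- NULL
    sel
  })
  islands_per_cluster <- vapply(clusters,
                                function(cl) length(unique(cl$island)), 0L)
  genes_per_cluster <- vapply(clusters, nrow, 0L)
  n_total <- nrow(gene_tab)
  n_unique <- sum(genes_per_cluster[islands_per_cluster == 1L])
  core <- which(islands_per_cluster == length(islands))
  structure(list(clusters = clusters,
                 n_genes_total = n_total,
                 n_unique = n_unique,
                 unique_fraction = n_unique / n_total,
                 core_clusters = core,
                 edges = edges),
            class = "gei_orthology")
}

#' @export
print.gei_orthology <- function(x, ...) {
  cat(sprintf(
    "<orthology> %d genes, %d clusters; %d unique (%.1f%%); %d core cluster(s)\n",
    x$n_genes_total, length(x$clusters), x$n_unique,
    100 * x$unique_fraction, length(x$core_clusters)))
  invisible(x)
}

#' Write orthology clusters as TSV
#'
#' @param orth A `gei_orthology`.
#' @param path Output path.
#' @export
write_cluster_table <- function(orth, path) {
  df <- do.call(rbind, lapply(seq_along(orth$clusters), function(i) {
    cbind(cluster_id = i, orth$clusters[[i]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
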