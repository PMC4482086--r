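test_that("identity matrices match hand-derived pairs and are symmetric", {
  m <- identity_matrix(c(a = "ACDE", b = "ACDE", c = "ACDF"))
  expect_equal(unname(m$identity["a", "b"]), 100)
  expect_equal(unname(m$identity["a", "c"]), 75)   # one substitution over 4
  expect_true(isSymmetric(m$identity))
  expect_equal(unname(diag(m$identity)), rep(100, 3))
  expect_true(all(m$identity >= 0 & m$identity <= 100))
  expect_equal(m$distance, 1 - m$identity / 100)
  # similarity counts positive-scoring substitutions (D/E is positive)
  expect_gte(m$similarity["a", "c"], m$identity["a", "c"])
  expect_error(identity_matrix(c(a = "ACDE")), "two sequences")
  expect_error(identity_matrix(c(a = "AC1E", b = "ACDE")), "non-amino-acid")
})

test_that("neighbour joining recovers a hand-checked additive quartet", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_equal(quartet_split_of_tree(tr), c("A", "B"))
  expect_equal(ls_quartet_split(d), c("A", "B"))
  # branch lengths of the generating tree: A=1, B=2, internal=1, C=3, D=4
  tips <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_setequal(round(tips, 6), c(1, 2, 3, 4))
  expect_error(nj_tree(d[1:2, 1:2]), "3 labels")
  d_bad <- d; d_bad[1, 2] <- NA; d_bad[2, 1] <- NA
  expect_error(nj_tree(d_bad), "non-finite")
})

test_that("NJ recovers random additive topologies and agrees with the LS oracle", {
  set.seed(23)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(x) stats::runif(x, 0.2, 1))
    d <- ape::cophenetic.phylo(true)
    got <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
    if (n == 4) expect_equal(ls_quartet_split(d), quartet_split_of_tree(got))
  }
})

test_that("NJ equals UPGMA topology on ultrametric distances", {
  set.seed(24)
  for (k in 1:10) {
    n <- sample(4:6, 1)
    clock <- ape::rcoal(n)
    d <- ape::cophenetic.phylo(clock)
    njt <- nj_tree(d)
    up <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
    expect_equal(ape::dist.topo(ape::unroot(njt), ape::unroot(up)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap support is seeded, bounded and maximal for clean clades", {
  set.seed(25)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s1 <- paste(sample(aa, 120, replace = TRUE), collapse = "")
  s2 <- paste(sample(aa, 120, replace = TRUE), collapse = "")
  jit <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(a) sample(setdiff(aa, a), 1), "")
    paste(ch, collapse = "")
  }
  aln <- c(A = s1, B = jit(s1, 2), C = s2, D = jit(s2, 2), E = jit(s2, 3))
  tr <- bootstrap_support(aln, n_replicates = 100, seed = 9)
  sup <- as.numeric(tr$node.label)
  expect_true(all(sup >= 0 & sup <= 1))
  # the A,B | C,D,E separation is unambiguous
  ab_node <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(sup[ab_node - ape::Ntip(tr)], 1.0)
  tr2 <- bootstrap_support(aln, n_replicates = 100, seed = 9)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr0 <- bootstrap_support(aln, n_replicates = 0)
  expect_null(tr0$node.label)
  expect_error(bootstrap_support(c(A = "K", B = "R", C = "K")), "degenerate")
  expect_error(bootstrap_support(c(A = "KL", B = "R", C = "KL")),
               "equal length")
})

test_that("logo information content follows the corrected entropy formula", {
  lg <- consensus_logo(c("AAAA", "AAAA", "AAAA", "AACA"),
                       small_sample_correction = FALSE)
  # columns 1,2,4 pure: IC = 2; column 3 has 3/4 A, 1/4 C
  expect_equal(lg$ic[c(1, 2, 4)], rep(2, 3))
  H3 <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(lg$ic[3], 2 - H3, tolerance = 1e-12)

  lgc <- consensus_logo(c("A", "A", "A", "A"))
  expect_equal(lgc$ic[1], 2 - 3 / (8 * log(2)), tolerance = 1e-12)
  lgu <- consensus_logo(c("A", "C", "G", "T"),
                        small_sample_correction = FALSE)
  expect_equal(lgu$ic[1], 0)
  expect_error(consensus_logo(c("AC", "A")), "equal length")

  # IC is monotonically non-increasing in column entropy
  cols <- list(c("A", "A", "A", "A"), c("A", "A", "A", "C"),
               c("A", "A", "C", "C"), c("A", "C", "G", "T"))
  ics <- vapply(cols, function(cl)
    consensus_logo(cl, small_sample_correction = FALSE)$ic[1], 0)
  expect_true(all(diff(ics) <= 1e-12))
})

test_that("RBH orthology handles identical, disjoint and hand-built proteomes", {
  set.seed(26)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rp <- function(n = 150) paste(sample(aa, n, replace = TRUE), collapse = "")
  pA <- c(g1 = rp(), g2 = rp())
  same <- rbh_orthology(list(i1 = pA, i2 = pA))
  expect_equal(same$n_unique, 0L)
  expect_equal(length(same$core_clusters), length(same$clusters))

  disjoint <- rbh_orthology(list(i1 = c(x = rp()), i2 = c(y = rp())))
  expect_equal(disjoint$n_unique, disjoint$n_genes_total)
  expect_equal(length(disjoint$core_clusters), 0L)

  # gene g in all three islands, gene h in exactly one
  g <- rp(); h <- rp()
  prot <- list(i1 = c(g = g, h = h), i2 = c(g = g), i3 = c(g = g))
  res <- rbh_orthology(prot)
  expect_equal(length(res$core_clusters), 1L)
  expect_equal(res$n_unique, 1L)
  core_members <- res$clusters[[res$core_clusters]]
  expect_setequal(core_members$gene, c("g", "g", "g"))

  empty_ok <- rbh_orthology(list(i1 = c(x = rp()), i2 = character(0)))
  expect_equal(empty_ok$n_unique, 1L)
})

test_that("RBH matches the brute-force oracle and recovers truth clusters", {
  for (s in 1:4) {
    pf <- make_protein_families(s, n_islands = sample(2:4, 1), n_core = 1,
                                n_shared = 1, n_unique_per_island = 1,
                                mutation_rate = 0.05)
    got <- rbh_orthology(pf$proteomes)
    want <- oracle_rbh(pf$proteomes)
    expect_equal(got$n_genes_total, want$n_genes_total)
    expect_equal(got$n_unique, want$n_unique)
    expect_equal(length(got$clusters), want$n_clusters)
    expect_equal(length(got$core_clusters), want$n_core)
    got_members <- lapply(got$clusters, function(cl)
      sort(paste(cl$island, cl$gene, sep = ":")))
    expect_setequal(got_members, want$membership)
  }
  # zero mutation: truth clusters recovered exactly
  pf0 <- make_protein_families(9, n_islands = 3, n_core = 1, n_shared = 1,
                               n_unique_per_island = 2, mutation_rate = 0)
  got0 <- rbh_orthology(pf0$proteomes)
  truth_members <- lapply(pf0$truth_clusters, function(cl)
    sort(paste(cl$island, cl$gene, sep = ":")))
  got_members <- lapply(got0$clusters, function(cl)
    sort(paste(cl$island, cl$gene, sep = ":")))
  expect_setequal(got_members, truth_members)
})

test_that("adding a duplicate island can only decrease the uniqueness fraction", {
  set.seed(27)
  pf <- make_protein_families(11, n_islands = 3, n_core = 1, n_shared = 1,
                              n_unique_per_island = 2, mutation_rate = 0.03)
  base <- rbh_orthology(pf$proteomes)
  dup <- pf$proteomes
  dup$island_dup <- pf$proteomes[[1]]
  more <- rbh_orthology(dup)
  expect_lte(more$unique_fraction, base$unique_fraction)
  expect_true(base$unique_fraction >= 0 && base$unique_fraction <= 1)
})
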