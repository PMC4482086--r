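toy_features <- function(int_strand, target_strand, int_first = TRUE,
                         gap = 300) {
  # three genes on one replicon: candidate integrase, target, bystander
  if (int_first) {
    int <- c(1000, 2199); tgt <- c(2200 + gap, 3199 + gap)
  } else {
    tgt <- c(1000, 2034); int <- c(2035 + gap, 3234 + gap)
  }
  rbind(
    gene_features("int", "r", int[1], int[2], int_strand, "CDS", "",
                  "integrase-like protein"),
    gene_features("tgt", "r", tgt[1], tgt[2], target_strand, "CDS", "dusA",
                  "tRNA-dihydrouridine synthase A"),
    gene_features("oth", "r", 9000, 9599, "+", "CDS", "gene3", "bystander"))
}

test_that("target genes are matched by name or full synonym phrase only", {
  f <- rbind(
    gene_features("a", "r", 10, 40, "+", "CDS", "dusA", ""),
    gene_features("b", "r", 50, 80, "+", "CDS", "DUSB", ""),
    gene_features("c", "r", 90, 130, "+", "CDS", "",
                  "tRNA-dihydrouridine synthase A"),
    gene_features("d", "r", 140, 170, "+", "CDS", "", "dihydrouridine"),
    gene_features("e", "r", 180, 220, "+", "CDS", "unrelated", "permease"))
  hits <- find_target_genes(f)
  expect_setequal(hits$id, c("a", "b", "c"))   # partial phrase "d" excluded
  expect_equal(hits$id, hits$id[order(hits$start)])
})

test_that("only the divergent 5'-to-5' arrangement qualifies as adjoined", {
  # target on +: its 5' end faces upstream; integrase must be "-" upstream
  cases <- list(
    list(int = "-", tgt = "+", int_first = TRUE,  expect_hit = TRUE),
    list(int = "+", tgt = "+", int_first = TRUE,  expect_hit = FALSE), # tandem
    list(int = "+", tgt = "-", int_first = TRUE,  expect_hit = FALSE), # convergent
    list(int = "-", tgt = "-", int_first = TRUE,  expect_hit = FALSE), # tandem
    list(int = "+", tgt = "-", int_first = FALSE, expect_hit = TRUE),
    list(int = "-", tgt = "-", int_first = FALSE, expect_hit = FALSE))
  for (cs in cases) {
    f <- toy_features(cs$int, cs$tgt, cs$int_first)
    target <- f[f$id == "tgt", ]
    got <- find_adjacent_integrase(target, f, max_gap = 1000)
    if (cs$expect_hit) {
      expect_s3_class(got, "gei_integrase_candidate")
      expect_equal(got$feature$id, "int")
      expect_equal(got$geometry, "divergent")
      expect_equal(got$gap_bp, 300L)
      expect_equal(got$association_class, "dusA")
    } else {
      expect_null(got)
    }
  }
})

test_that("association respects max_gap and reports ambiguity", {
  f <- toy_features("-", "+", int_first = TRUE, gap = 1500)
  target <- f[f$id == "tgt", ]
  expect_null(find_adjacent_integrase(target, f, max_gap = 1000))
  expect_s3_class(find_adjacent_integrase(target, f, max_gap = 2000),
                  "gei_integrase_candidate")

  # two equally-near divergent candidates on both sides
  f2 <- rbind(
    gene_features("intL", "r", 1000, 1999, "-", "CDS", "", "candidate L"),
    gene_features("tgt", "r", 2300, 3334, "+", "CDS", "dusA", "target"),
    gene_features("intR", "r", 3635, 4634, "-", "CDS", "", "candidate R"))
  # intR is convergent to tgt (3' facing), so no ambiguity there; make a
  # true tie with a second divergent upstream candidate at equal gap
  f3 <- rbind(
    gene_features("intA", "r", 1000, 1999, "-", "CDS", "", "candidate A"),
    gene_features("tgt", "r", 2300, 3334, "+", "CDS", "dusA", "target"),
    gene_features("intB", "r", 1000, 1999, "-", "CDS", "", "candidate B"))
  expect_error(find_adjacent_integrase(f3[f3$id == "tgt", ], f3),
               "ambiguous")
  expect_equal(find_adjacent_integrase(f2[f2$id == "tgt", ], f2)$feature$id,
               "intL")
})

test_that("association is invariant under reverse-complementing the replicon", {
  wt <- make_wildtype(31, genome_len = 40000)
  tr <- implant_island(wt, 32, island_len = 9000, band = c(5000, 15000),
                       core_mismatches = 0, n_decoys = 0)
  g <- tr$integrated
  target <- g$features[g$features$id == tr$target_id, ]
  fwd <- find_adjacent_integrase(target, g$features)
  rc <- revcomp_annotation(g$replicon, g$features)
  target_rc <- rc$features[rc$features$id == tr$target_id, ]
  rev <- find_adjacent_integrase(target_rc, rc$features)
  expect_equal(rev$feature$id, fwd$feature$id)
  expect_equal(rev$geometry, "divergent")
  expect_equal(rev$gap_bp, fwd$gap_bp)
})

test_that("motif scan finds the ordered catalytic pentad in the C-terminal window", {
  r <- motif_check("MRAHARAHAYA", window_frac = 1)
  expect_true(r$pass)
  expect_equal(r$positions, c(2L, 4L, 6L, 8L, 10L))
  expect_false(motif_check(strrep("A", 50))$pass)
  expect_error(motif_check("MKL1"), "non-amino-acid")

  # pentad only in the N-terminal 40% fails under the default window
  prot <- paste0("MARAHARAHAYA", strrep("G", 60))
  expect_false(motif_check(prot)$pass)
  expect_true(motif_check(prot, window_frac = 1)$pass)

  # passing stays passing when residues are prepended (window only grows)
  base <- paste0(strrep("G", 10), "RAHARAHAY")
  expect_true(motif_check(base)$pass)
  set.seed(5)
  for (k in 1:10) {
    pre <- paste(sample(c("G", "S", "T"), k * 7, replace = TRUE),
                 collapse = "")
    expect_true(motif_check(paste0(pre, base))$pass)
  }
})

test_that("homology screen passes self, rejects shuffles, breaks ties by order", {
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, 200, replace = TRUE), collapse = "")
  panel <- c(refA = ref,
             refB = paste(sample(aa, 180, replace = TRUE), collapse = ""))
  self <- homology_screen(ref, panel)
  expect_equal(self$score_ratio, 1.0)
  expect_true(self$pass)
  expect_equal(self$best_reference, "refA")

  # shuffled queries of identical composition almost never pass
  fails <- 0L
  for (k in 1:100) {
    shuf <- paste(sample(strsplit(ref, "")[[1]]), collapse = "")
    if (!homology_screen(shuf, panel)$pass) fails <- fails + 1L
  }
  expect_gte(fails, 99L)

  dup <- c(first = ref, second = ref)
  expect_equal(homology_screen(ref, dup)$best_reference, "first")
  expect_error(homology_screen(ref, character(0)), "reference")
})
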