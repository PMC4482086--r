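test_that("a planted imperfect 21-mer pair is found with the right mismatch count", {
  set.seed(41)
  s <- random_seq(500)
  s <- plant_repeat(s, 100, 400, mm_at = 3)   # 1 outer-arm mismatch
  rep <- replicon("toy", s, "linear")
  hits <- find_direct_repeats(rep, anchor = 100, anchor_radius = 60,
                              window = 1000, band = c(250, 350))
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$attL_start[1], 100L)
  expect_equal(hits$attR_start[1], 400L)
  expect_equal(hits$mismatches[1], 1L)
  expect_equal(hits$island_size[1], 321L)

  # no repeated seed between windows -> empty result
  set.seed(42)
  s2 <- random_seq(400)
  rep2 <- replicon("toy2", s2, "linear")
  expect_equal(nrow(find_direct_repeats(rep2, anchor = 50,
                                        anchor_radius = 40, window = 800)),
               0L)
})

test_that("ranking puts an exact pair above a decoy with more mismatches", {
  set.seed(43)
  s <- random_seq(2000)
  s <- plant_repeat(s, 300, 1500, mm_at = integer(0))      # true, 0 mm
  s <- plant_repeat(s, 350, 1400, mm_at = c(2, 3, 4))      # decoy, 3 mm
  rep <- replicon("toy", s, "linear")
  hits <- find_direct_repeats(rep, anchor = 330, anchor_radius = 100,
                              window = 4000, band = c(1000, 1400))
  # top hit: the exact pair (registration may slide if flanks happen to
  # match, so check the diagonal rather than the absolute position)
  expect_equal(hits$attR_start[1] - hits$attL_start[1], 1200L)
  expect_equal(hits$mismatches[1], 0L)
  expect_lte(abs(hits$attL_start[1] - 300L), 5L)
  # the decoy diagonal is present but ranked below the exact pair
  decoy <- hits[hits$attR_start - hits$attL_start == 1050L, ]
  expect_equal(nrow(decoy), 1L)
  expect_gt(which(hits$attR_start - hits$attL_start == 1050L), 1L)
  expect_gt(decoy$mismatches, 0L)
})

test_that("find_direct_repeats agrees with the all-pairs Hamming oracle", {
  set.seed(44)
  for (k in 1:8) {
    n <- sample(600:2500, 1)
    s <- random_seq(n)
    n_plant <- sample(0:3, 1)
    grid <- sample(seq(30, n - 60, by = 60))   # distinct, non-overlapping
    spacings <- integer(0)
    for (p in seq_len(n_plant)) {
      pos <- sort(grid[c(2 * p - 1, 2 * p)])
      if (diff(pos) < 25 || diff(pos) %in% spacings) next
      spacings <- c(spacings, diff(pos))
      s <- plant_repeat(s, pos[1], pos[2],
                        mm_at = sample(c(2:4, 18:20), sample(0:3, 1)))
    }
    rep <- replicon("p", s, "linear")
    got <- find_direct_repeats(rep, anchor = ceiling(n / 2),
                               anchor_radius = n, window = 2 * n,
                               band = c(1, n))
    want <- oracle_direct_repeats(s)
    # every reported pair must be a per-diagonal oracle optimum...
    if (nrow(got)) {
      for (i in seq_len(nrow(got))) {
        d <- got$attR_start[i] - got$attL_start[i]
        expect_false(is.null(want[[as.character(d)]]))
        expect_equal(got$mismatches[i], want[[as.character(d)]]$mm)
        expect_true(got$attL_start[i] %in% want[[as.character(d)]]$starts)
      }
    }
    # ...and every oracle diagonal must be reported
    expect_setequal(as.character(got$attR_start - got$attL_start),
                    as.character(names(want)))
  }
})

make_fixture <- function(seed, m = 1, ...) {
  wt <- make_wildtype(seed, genome_len = 60000)
  tr <- implant_island(wt, seed + 7, island_len = 12000,
                       band = c(8000, 20000), core_mismatches = m, ...)
  calls <- scan_replicon(tr$integrated$replicon, tr$integrated$features,
                         pipeline_config(island_band_lo = 8000L,
                                         island_band_hi = 20000L))
  list(truth = tr, call = calls[[1]])
}

test_that("island calls carry consistent size arithmetic and enclose the integrase", {
  fx <- make_fixture(51)
  call <- fx$call
  expect_s3_class(call, "gei_island")
  expect_equal(call$size, span_size(call$start, call$end))
  intf <- call$integrase$feature
  expect_true(intf$start >= call$start && intf$end <= call$end)
  expect_equal(call$start, fx$truth$island_start)
  expect_equal(call$end, fx$truth$island_end)
})

test_that("no-call diagnostics name the failing criterion", {
  fx <- make_fixture(52)
  g <- fx$truth$integrated
  target <- g$features[g$features$id == "dusA01", ]
  integ <- find_adjacent_integrase(target, g$features)
  # a repeat pair that lies entirely outside the integrase span
  fake <- data.frame(attL_start = 100L, attL_end = 120L, attR_start = 300L,
                     attR_end = 320L,
                     attL_seq = strrep("A", 21), attR_seq = strrep("A", 21),
                     mismatches = 0L, island_size = 221L, in_band = FALSE)
  res <- call_island(g$replicon, target, integ, fake)
  expect_s3_class(res, "gei_nocall")
  expect_match(res$diagnostics$reason[1], "integrase not enclosed")
})

test_that("excision restores the wild type and conserves sequence length", {
  for (m in 0:2) {
    fx <- make_fixture(60 + m, m = m)
    g <- fx$truth$integrated
    ex <- reconstruct_excision(g$replicon, fx$call, g$features)
    expect_identical(ex$restored_seq, fx$truth$wildtype$replicon$seq)
    expect_identical(ex$circle_seq, fx$truth$expected_circle)
    # mechanistic conservation: one core copy on each product
    expect_equal(nchar(ex$circle_seq) + nchar(ex$restored_seq),
                 g$replicon$length)
    # island-span bookkeeping: the linearised span writes the core twice
    expect_equal(nchar(ex$island_span_seq), nchar(ex$circle_seq) + ex$core_len)
    expect_equal(ex$attP_seq, fx$truth$attL_seq)
    expect_equal(ex$attB_seq, fx$truth$attR_seq)
    v <- validate_restored_gene(ex, fx$truth$wildtype_cds)
    expect_true(v$has_start_codon)
    expect_true(v$no_internal_stop)
    expect_equal(v$identity_pct, 100)
  }
})

test_that("a frameshifted replacement segment is flagged by the ORF report", {
  fx <- make_fixture(70, m = 0)
  cds <- fx$truth$chimeric_cds
  rep_ok <- dusaGEI:::orf_report(cds)
  expect_true(rep_ok$has_start_codon && rep_ok$no_internal_stop)
  # delete one base early in the replacement segment: frameshift
  cds_fs <- paste0(substr(cds, 1, 5), substr(cds, 7, nchar(cds)))
  rep_fs <- dusaGEI:::orf_report(cds_fs)
  expect_false(rep_fs$no_internal_stop)
})

test_that("empty wild-type CDS omits the identity field", {
  fx <- make_fixture(72, m = 0)
  ex <- reconstruct_excision(fx$truth$integrated$replicon, fx$call,
                             fx$truth$integrated$features)
  v <- validate_restored_gene(ex, NULL)
  expect_null(v$identity_pct)
  expect_named(v, c("has_start_codon", "no_internal_stop", "length_aa"))
})

test_that("junction PCR amplifies only the template carrying its junction", {
  fx <- make_fixture(80, m = 1)
  g <- fx$truth$integrated
  ex <- reconstruct_excision(g$replicon, fx$call, g$features)
  pr <- design_junction_primers(ex)
  circ <- in_silico_pcr(ex$circle_seq, pr$circle$fwd, pr$circle$rev,
                        topology = "circular")
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$product_len, pr$circle$expected_len)
  expect_equal(nrow(in_silico_pcr(g$replicon$seq, pr$circle$fwd,
                                  pr$circle$rev)), 0L)
  rest <- in_silico_pcr(ex$restored_seq, pr$restored$fwd, pr$restored$rev)
  expect_equal(nrow(rest), 1L)
  expect_equal(rest$product_len, pr$restored$expected_len)
  expect_equal(nrow(in_silico_pcr(g$replicon$seq, pr$restored$fwd,
                                  pr$restored$rev)), 0L)
  # cross-template: circle primers on the restored genome and vice versa
  expect_equal(nrow(in_silico_pcr(ex$restored_seq, pr$circle$fwd,
                                  pr$circle$rev)), 0L)
  expect_equal(nrow(in_silico_pcr(ex$circle_seq, pr$restored$fwd,
                                  pr$restored$rev, topology = "circular")),
               0L)
})

test_that("in silico PCR coordinate arithmetic and misses behave as specified", {
  set.seed(90)
  s <- random_seq(100)
  fwd <- substr(s, 1, 20)
  rev <- revcomp(substr(s, 81, 100))
  am <- in_silico_pcr(s, fwd, rev)
  expect_equal(nrow(am), 1L)
  expect_equal(am$product_len, 100L)
  expect_equal(am$fwd_pos, 1L)
  expect_equal(am$rev_pos, 100L)
  absent <- paste(rep("ACGTT", 4), collapse = "")
  expect_equal(nrow(in_silico_pcr(s, absent, rev)), 0L)
  expect_error(in_silico_pcr(s, "ACGTACGTAC", rev), "15")
  # a 3'-terminal mismatch blocks extension even when mismatches are allowed
  fwd_bad <- paste0(substr(fwd, 1, 19),
                    setdiff(c("A", "C", "G", "T"), substr(fwd, 20, 20))[1])
  expect_equal(nrow(in_silico_pcr(s, fwd_bad, rev, max_mismatches = 2)), 0L)
  fwd_mid <- fwd
  substr(fwd_mid, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(fwd, 5, 5))[1]
  expect_equal(nrow(in_silico_pcr(s, fwd_mid, rev, max_mismatches = 2)), 1L)
})

test_that("island size summaries compute mean, min and max", {
  s <- summarize_island_sizes(c(1000, 2000, 6000))
  expect_equal(s$mean_kb, 3)
  expect_equal(s$min_bp, 1000)
  expect_equal(s$max_bp, 6000)
  expect_equal(s$n, 3L)
})
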