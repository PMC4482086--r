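#' Seed-and-extend search for semiconserved direct repeats
#'
#' Islands that integrate into the dusA 5' region are bounded by a pair of
#' ~21 bp imperfect direct repeats (attL/attR). The search enumerates exact
#' `seed_len`-mer matches between a window anchored on the target gene's 5'
#' end and a larger flanking search window (same strand only - these are
#' direct, not inverted, repeats), extends each seed to `core_len` at the
#' mismatch-minimising offset, and ranks surviving pairs.
#'
#' Ranking: fewest mismatches first; then pairs whose implied island size
#' falls inside the prior band (default 30-60 kb, the typical island size
#' range) before out-of-band pairs, longer implied islands first within the
#' band; then ascending coordinate. Core windows containing N are excluded.
#'
#' @param rep A [replicon()].
#' @param anchor Coordinate of the target gene's 5' end.
#' @param anchor_radius Half-width of the anchor window (bp).
#' @param window Total width of the flanking search window (bp).
#' @param core_len Repeat core length (default 21 bp).
#' @param seed_len Exact-seed length (default 12 bp).
#' @param max_mismatches Maximum Hamming mismatches over the core.
#' @param band Island-size prior band used for ranking, bp (low, high).
#' @param max_seed_occ Seeds occurring more often than this in the search
#'   window are skipped (low-complexity guard).
#' @return A ranked data frame of class `gei_attrepeats` with columns
#'   `attL_start`, `attL_end`, `attR_start`, `attR_end`, `attL_seq`,
#'   `attR_seq`, `mismatches`, `island_size`, `in_band`. Zero rows when no
#'   repeated seed exists between the windows.
#' @export
find_direct_repeats <- function(rep, anchor, anchor_radius = 2000,
                                window = 200000, core_len = 21,
                                seed_len = 12, max_mismatches = 3,
                                band = c(30000, 60000),
                                max_seed_occ = 100) {
  stopifnot(inherits(rep, "gei_replicon"))
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > rep$length)
    stop("anchor lies outside the replicon")
  if (core_len < seed_len) stop("core_len must be >= seed_len")
  N <- rep$length
  a_lo <- max(1L, anchor - as.integer(anchor_radius))
  a_hi <- min(N, anchor + as.integer(anchor_radius))
  s_lo <- max(1L, anchor - as.integer(window) %/% 2L)
  s_hi <- min(N, anchor + as.integer(window) %/% 2L)

  kmer_starts <- function(lo, hi) {
    if (hi - lo + 1L < seed_len) integer(0) else lo:(hi - seed_len + 1L)
  }
  pa <- kmer_starts(a_lo, a_hi)
  ps <- kmer_starts(s_lo, s_hi)
  if (!length(pa) || !length(ps)) stop("anchor window too small for seeds")
  ka <- substring(rep$seq, pa, pa + seed_len - 1L)
  keepa <- !grepl("N", ka, fixed = TRUE)
  pa <- pa[keepa]; ka <- ka[keepa]
  if (!length(pa)) stop("anchor window contains no usable (N-free) seed")
  ks <- substring(rep$seq, ps, ps + seed_len - 1L)
  keeps <- !grepl("N", ks, fixed = TRUE)
  ps <- ps[keeps]; ks <- ks[keeps]

  # hash-join the anchor and search k-mer sets
  anchor_map <- split(pa, ka)
  in_anchor <- ks %in% names(anchor_map)
  search_map <- split(ps[in_anchor], ks[in_anchor])
  pairs_L <- integer(0); pairs_R <- integer(0)
  for (km in names(search_map)) {
    qa <- anchor_map[[km]]; qs <- search_map[[km]]
    if (length(qs) > max_seed_occ) next
    pp <- rep(qa, each = length(qs)); qq <- rep(qs, length(qa))
    keep <- abs(pp - qq) >= core_len
    if (!any(keep)) next
    pp <- pp[keep]; qq <- qq[keep]
    pairs_L <- c(pairs_L, pmin(pp, qq))
    pairs_R <- c(pairs_R, pmax(pp, qq))
  }
  empty <- structure(
    data.frame(attL_start = integer(0), attL_end = integer(0),
               attR_start = integer(0), attR_end = integer(0),
               attL_seq = character(0), attR_seq = character(0),
               mismatches = integer(0), island_size = integer(0),
               in_band = logical(0)),
    class = c("gei_attrepeats", "data.frame"))
  if (!length(pairs_L)) return(empty)
  dedup <- !duplicated(paste(pairs_L, pairs_R))
  pairs_L <- pairs_L[dedup]; pairs_R <- pairs_R[dedup]

  # extend each seed pair to core_len at the best offset
  slack <- core_len - seed_len
  best <- vector("list", length(pairs_L))
  for (i in seq_along(pairs_L)) {
    p <- pairs_L[i]; q <- pairs_R[i]
    bestmm <- Inf; besto <- NA_integer_
    for (o in 0:slack) {
      lp <- p - o; lq <- q - o
      if (lp < 1L || lq + core_len - 1L > N) next
      wa <- substr(rep$seq, lp, lp + core_len - 1L)
      wb <- substr(rep$seq, lq, lq + core_len - 1L)
      if (grepl("N", wa, fixed = TRUE) || grepl("N", wb, fixed = TRUE)) next
      mm <- hamming(wa, wb)
      if (mm < bestmm) { bestmm <- mm; besto <- o }
    }
    if (!is.finite(bestmm) || bestmm > max_mismatches) next
    lp <- p - besto; lq <- q - besto
    best[[i]] <- data.frame(
      attL_start = lp, attL_end = lp + core_len - 1L,
      attR_start = lq, attR_end = lq + core_len - 1L,
      attL_seq = substr(rep$seq, lp, lp + core_len - 1L),
      attR_seq = substr(rep$seq, lq, lq + core_len - 1L),
      mismatches = as.integer(bestmm),
      stringsAsFactors = FALSE)
  }
  best <- Filter(Negate(is.null), best)
  if (!length(best)) return(empty)
  out <- do.call(rbind, best)
  out <- out[!duplicated(paste(out$attL_start, out$attR_start)), , drop = FALSE]
  out <- out[out$attL_end < out$attR_start, , drop = FALSE]   # non-overlapping
  if (!nrow(out)) return(empty)
  out$island_size <- span_size(out$attL_start, out$attR_end)
  out$in_band <- out$island_size >= band[1] & out$island_size <= band[2]
  ord <- order(out$mismatches, !out$in_band,
               ifelse(out$in_band, -out$island_size, 0L), out$attL_start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gei_attrepeats", "data.frame"))
}

#' Call island boundaries from ranked repeat pairs
#'
#' Selects the top-ranked repeat pair that (a) encloses the integrase CDS
#' within `[attL_start, attR_end]` and (b) places exactly one core copy
#' inside (or abutting) the target gene's annotated extent - the geometry
#' produced by site-specific integration into the gene's 5' region. The
#' island interval is `[attL first base, attR last base]`, the convention
#' under which published termini and sizes satisfy size = end - start + 1.
#'
#' @param rep A [replicon()].
#' @param target Target gene feature row.
#' @param integrase A `gei_integrase_candidate` from
#'   [find_adjacent_integrase()].
#' @param repeats Ranked repeats from [find_direct_repeats()].
#' @param compute_tri Compute the trinucleotide atypicality score (adds a
#'   seeded empirical-null simulation; see [tri_zscore()]).
#' @param tri_n_null,tri_seed Null size and seed for [tri_zscore()].
#' @return A `gei_island` on success; otherwise a `gei_nocall` whose
#'   `diagnostics` data frame lists each rejected pair and the reason.
#' @export
call_island <- function(rep, target, integrase, repeats,
                        compute_tri = FALSE, tri_n_null = 200,
                        tri_seed = 1L) {
  if (!nrow(repeats)) {
    return(structure(list(replicon_id = rep$id,
                          reason = "no repeat pairs supplied",
                          diagnostics = data.frame()),
                     class = "gei_nocall"))
  }
  intf <- integrase$feature
  reasons <- character(nrow(repeats))
  for (i in seq_len(nrow(repeats))) {
    r <- repeats[i, ]
    if (!(intf$start >= r$attL_start && intf$end <= r$attR_end)) {
      reasons[i] <- "integrase not enclosed"
      next
    }
    in_target <- function(s, e)
      s <= target$end + 1L && e >= target$start - 1L
    nhit <- in_target(r$attL_start, r$attL_end) +
            in_target(r$attR_start, r$attR_end)
    if (nhit != 1L) {
      reasons[i] <- sprintf("%d core copies touch the target gene", nhit)
      next
    }
    island_seq <- subsequence(rep, r$attL_start, r$attR_end)
    gc <- gc_percent(island_seq)
    tri <- NA_real_
    if (compute_tri) {
      prof <- tri_profile(island_seq, circular = FALSE)
      tri <- tri_zscore(prof, rep, island_len = nchar(island_seq),
                        n_null = tri_n_null, seed = tri_seed)$score
    }
    return(structure(list(replicon_id = rep$id,
                          start = r$attL_start, end = r$attR_end,
                          size = span_size(r$attL_start, r$attR_end),
                          att = r, integrase = integrase,
                          gc_percent = gc, tri_score = tri,
                          provenance = "detected"),
                     class = "gei_island"))
  }
  diag <- cbind(repeats, reason = reasons)
  structure(list(replicon_id = rep$id,
                 reason = "no repeat pair satisfies the island criteria",
                 diagnostics = diag),
            class = "gei_nocall")
}

#' @export
print.gei_island <- function(x, ...) {
  cat(sprintf(
    "<island call> %s:%d..%d (%d bp), att %d mismatches, GC %.1f%%%s\n",
    x$replicon_id, x$start, x$end, x$size, x$att$mismatches, x$gc_percent,
    if (is.na(x$tri_score)) "" else sprintf(", tri score %.2f", x$tri_score)))
  invisible(x)
}

#' @export
print.gei_nocall <- function(x, ...) {
  cat(sprintf("<no island call> %s: %s\n", x$replicon_id, x$reason))
  if (nrow(x$diagnostics)) {
    cat("rejected pairs:\n")
    print(utils::head(as.data.frame(
      x$diagnostics)[, c("attL_start", "attR_start", "mismatches", "reason")]))
  }
  invisible(x)
}

orf_across_core <- function(seq, core_start, core_end, strand = "+") {
  # Maximal ORF (start codon .. stop codon, code 11) covering the core on
  # the given strand; returns the CDS string and its coordinates on `seq`,
  # or NULL when no reading frame spans the core stop-free.
  N <- nchar(seq)
  if (strand == "-") {
    res <- orf_across_core(revcomp(seq), N - core_end + 1L,
                           N - core_start + 1L, "+")
    if (is.null(res)) return(NULL)
    return(list(cds = res$cds, start = N - res$end + 1L,
                end = N - res$start + 1L, strand = "-"))
  }
  best <- NULL
  for (frame in 0:2) {
    starts <- seq(1L + frame, N - 2L, by = 3L)
    cods <- substring(seq, starts, starts + 2L)
    ci_lo <- which(starts <= core_start)
    ci_hi <- which(starts + 2L >= core_end)
    if (!length(ci_lo) || !length(ci_hi)) next
    i_core_lo <- max(ci_lo); i_core_hi <- min(ci_hi)
    stops <- which(cods %in% STOP_CODONS)
    stop_after <- stops[stops >= i_core_hi]
    if (!length(stop_after)) next
    i_stop <- stop_after[1]
    stop_before <- stops[stops < i_core_lo]
    i_prev <- if (length(stop_before)) max(stop_before) else 0L
    cand_idx <- seq(i_prev + 1L, i_core_lo)
    is_start <- which(cods[cand_idx] %in% START_CODONS)
    if (!length(is_start)) next
    i_start <- cand_idx[is_start[1]]          # furthest-upstream start codon
    cds <- paste(cods[i_start:i_stop], collapse = "")
    if (is.null(best) || nchar(cds) > nchar(best$cds))
      best <- list(cds = cds, start = starts[i_start],
                   end = starts[i_stop] + 2L, strand = "+")
  }
  best
}

#' Reconstruct the excision products of a called island
#'
#' Models integrase-catalysed excision via recombination between the attL
#' and attR cores: the circular intermediate is
#' `[attL_start, attR_start - 1]` circularised (it carries exactly one core
#' copy, attP, at its origin), and the restored chromosome is the replicon
#' with that interval deleted (the downstream attR copy stays in place and
#' becomes attB, reuniting the original target-gene 5' end with its body).
#' The linearised island span `[attL_start, attR_end]` - the interval form
#' in which island sizes are reported, with the core written at both
#' termini - is also returned.
#'
#' @param rep A [replicon()].
#' @param call A `gei_island` (detected or truth provenance).
#' @param features Optional feature table; features other than the target
#'   gene that straddle a deletion boundary are reported as warnings.
#' @return A `gei_excision` list: `circle_seq`, `island_span_seq`,
#'   `restored_seq`, `restored_gene_cds`, `restored_gene_coords`,
#'   `attP_seq`, `attB_seq`, `core_len`, `orf_report`, `warnings`.
#' @export
reconstruct_excision <- function(rep, call, features = NULL) {
  stopifnot(inherits(rep, "gei_replicon"), inherits(call, "gei_island"))
  a <- call$att
  core_len <- nchar(a$attL_seq)
  N <- rep$length
  circle_seq <- substr(rep$seq, a$attL_start, a$attR_start - 1L)
  island_span_seq <- substr(rep$seq, a$attL_start, a$attR_end)
  restored_seq <- paste0(substr(rep$seq, 1L, a$attL_start - 1L),
                         substr(rep$seq, a$attR_start, N))
  attB_pos <- a$attL_start       # retained core position on the restored seq
  warnings <- character(0)
  if (!is.null(features)) {
    tgt_id <- call$integrase$target$id
    for (k in seq_len(nrow(features))) {
      f <- features[k, ]
      if (f$id == tgt_id) next
      inside <- f$start >= a$attL_start && f$end <= a$attR_end
      outside <- f$end < a$attL_start || f$start > a$attR_end
      if (!inside && !outside)
        warnings <- c(warnings, sprintf(
          "feature %s (%d..%d) straddles an excision boundary",
          f$id, f$start, f$end))
    }
  }
  strand <- call$integrase$target$strand
  orf <- orf_across_core(restored_seq, attB_pos, attB_pos + core_len - 1L,
                         strand)
  if (is.null(orf))
    stop("restored CDS unlocatable: no ORF spans the retained core")
  structure(list(circle_seq = circle_seq,
                 island_span_seq = island_span_seq,
                 restored_seq = restored_seq,
                 restored_gene_cds = orf$cds,
                 restored_gene_coords = c(start = orf$start, end = orf$end),
                 attP_seq = substr(circle_seq, 1L, core_len),
                 attB_seq = a$attR_seq,
                 attB_pos = attB_pos,
                 core_len = core_len,
                 orf_report = orf_report(orf$cds),
                 warnings = warnings),
            class = "gei_excision")
}

#' @export
print.gei_excision <- function(x, ...) {
  cat(sprintf(
    "<excision products> circle %d bp (attP %s...), restored %d bp, gene %d aa\n",
    nchar(x$circle_seq), substr(x$attP_seq, 1, 8), nchar(x$restored_seq),
    x$orf_report$length_aa))
  invisible(x)
}

#' Validate the restored target gene
#'
#' Checks the reading frame reconstructed across the retained core: start
#' codon (ATG/GTG/TTG under code table 11), absence of internal stops, and
#' length; when the wild-type CDS is supplied, global-alignment percent
#' identity against it.
#'
#' @param products A `gei_excision` from [reconstruct_excision()].
#' @param wildtype_cds Optional wild-type CDS DNA string.
#' @return List with `has_start_codon`, `no_internal_stop`, `length_aa`
#'   and, when `wildtype_cds` is given, `identity_pct`.
#' @export
validate_restored_gene <- function(products, wildtype_cds = NULL) {
  stopifnot(inherits(products, "gei_excision"))
  rep_ <- products$orf_report
  out <- list(has_start_codon = rep_$has_start_codon,
              no_internal_stop = rep_$no_internal_stop,
              length_aa = rep_$length_aa)
  if (!is.null(wildtype_cds) && nzchar(wildtype_cds)) {
    out$identity_pct <-
      if (identical(products$restored_gene_cds, toupper(wildtype_cds))) 100
      else dna_global_identity(products$restored_gene_cds, wildtype_cds)
  }
  out
}

match_primer_sites <- function(text, primer, max_mismatches, three_prime) {
  # Start positions (1-based) where `primer` matches `text` with at most
  # `max_mismatches`, requiring the 3 bases at the primer's 3' terminus to
  # match exactly. `three_prime` is "right" for a forward primer and "left"
  # for the plus-strand image of a reverse primer.
  N <- nchar(text); L <- nchar(primer)
  if (L > N) return(integer(0))
  if (max_mismatches == 0L) {
    hits <- gregexpr(primer, text, fixed = TRUE)[[1]]
    return(if (hits[1] == -1L) integer(0) else as.integer(hits))
  }
  t <- utf8ToInt(text); p <- utf8ToInt(primer)
  npos <- N - L + 1L
  mm <- integer(npos)
  for (j in seq_len(L))
    mm <- mm + (t[j:(npos + j - 1L)] != p[j])
  exact_idx <- if (three_prime == "right") (L - 2L):L else 1:3
  ok3 <- rep(TRUE, npos)
  for (j in exact_idx)
    ok3 <- ok3 & (t[j:(npos + j - 1L)] == p[j])
  which(mm <= max_mismatches & ok3)
}

#' In silico PCR
#'
#' Predicts amplicons for a primer pair on a template: binding sites of the
#' forward primer on the plus strand and of the reverse primer on the minus
#' strand (both within `max_mismatches`, with the 3 bases at each primer's
#' 3' terminus required to match exactly, modelling polymerase extension
#' specificity), and every convergent pairing up to `max_product` bp. On
#' circular templates products may span the origin. Junction-specific
#' primer pairs therefore yield a product only on the template carrying
#' that junction - the logic of the excision assay.
#'
#' @param template DNA string.
#' @param fwd,rev Primer sequences, each written 5' to 3' on its own strand
#'   (the reverse primer anneals to the plus strand shown).
#' @param topology `"linear"` or `"circular"`.
#' @param max_mismatches Allowed mismatches outside the 3'-terminal 3 bases.
#' @param max_product Maximum reported product length (bp).
#' @return Data frame with `fwd_pos` (forward primer 5' position),
#'   `rev_pos` (reverse primer 5' position on the plus strand) and
#'   `product_len`; zero rows when there is no product. Product length runs
#'   from the forward 5' end through the reverse 5' end inclusive.
#' @export
in_silico_pcr <- function(template, fwd, rev,
                          topology = c("linear", "circular"),
                          max_mismatches = 0, max_product = 10000) {
  topology <- match.arg(topology)
  template <- toupper(template); fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 bp")
  N <- nchar(template)
  text <- template
  if (topology == "circular") {
    ext <- min(max_product - 1L, N)
    text <- paste0(template, substr(template, 1L, ext))
  }
  rev_rc <- revcomp(rev)
  f_sites <- match_primer_sites(text, fwd, as.integer(max_mismatches), "right")
  r_sites <- match_primer_sites(text, rev_rc, as.integer(max_mismatches), "left")
  out <- data.frame(fwd_pos = integer(0), rev_pos = integer(0),
                    product_len = integer(0))
  if (!length(f_sites) || !length(r_sites)) return(out)
  f_sites <- f_sites[f_sites <= N]            # dedup circular images
  Lf <- nchar(fwd); Lr <- nchar(rev)
  for (f in f_sites) {
    for (r in r_sites) {
      rev5 <- r + Lr - 1L                      # reverse primer 5' end
      len <- rev5 - f + 1L
      if (r < f || len > max_product) next
      if (len < max(Lf, Lr)) next
      out <- rbind(out, data.frame(
        fwd_pos = f,
        rev_pos = if (rev5 > N) rev5 - N else rev5,
        product_len = len))
    }
  }
  unique(out)
}

#' Design junction-diagnostic primer pairs
#'
#' Builds the two primer pairs of the excision assay from reconstructed
#' products: one straddling the circle's attP junction (yields a product
#' only on the circularised island) and one straddling the restored attB
#' junction (yields a product only on the excised chromosome). On the
#' integrated chromosome both pairs point away from each other across the
#' island and yield nothing.
#'
#' @param products A `gei_excision`.
#' @param primer_len Primer length (bp).
#' @param offset Distance from the junction core to each primer's 3' end
#'   (bp).
#' @return List with `circle` and `restored`, each `list(fwd, rev,
#'   expected_len)`.
#' @export
design_junction_primers <- function(products, primer_len = 20, offset = 60) {
  stopifnot(inherits(products, "gei_excision"))
  core <- products$core_len
  M <- nchar(products$circle_seq)
  if (M < core + 2 * (offset + primer_len))
    stop("circle too short for the requested primer layout")
  cs <- products$circle_seq
  circ_fwd <- substr(cs, M - offset - primer_len + 1L, M - offset)
  circ_rev <- revcomp(substr(cs, core + offset + 1L,
                             core + offset + primer_len))
  rs <- products$restored_seq
  b <- products$attB_pos
  if (b - offset - primer_len < 1L ||
      b + core + offset + primer_len - 1L > nchar(rs))
    stop("restored junction too close to the sequence end for primers")
  rest_fwd <- substr(rs, b - offset - primer_len, b - offset - 1L)
  rest_rev <- revcomp(substr(rs, b + core + offset,
                             b + core + offset + primer_len - 1L))
  expected <- core + 2L * (offset + primer_len)
  list(circle = list(fwd = circ_fwd, rev = circ_rev,
                     expected_len = expected),
       restored = list(fwd = rest_fwd, rev = rest_rev,
                       expected_len = expected))
}

#' Write island calls as TSV
#'
#' @param calls List of `gei_island` objects.
#' @param path Output path.
#' @param header Optional named list echoed as comment lines.
#' @export
write_island_table <- function(calls, path, header = NULL) {
  df <- do.call(rbind, lapply(calls, function(x) {
    data.frame(replicon = x$replicon_id,
               coordinates = sprintf("%d..%d", x$start, x$end),
               size_bp = x$size, gc_percent = x$gc_percent,
               att_mismatches = x$att$mismatches,
               tri_score = x$tri_score, stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- data.frame(replicon = character(0), coordinates = character(0),
                     size_bp = integer(0), gc_percent = numeric(0),
                     att_mismatches = integer(0), tri_score = numeric(0))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Summarise island sizes
#'
#' Mean (kb), minimum and maximum (bp) of a vector of island sizes, the
#' summary reported for island survey tables.
#'
#' @param sizes_bp Numeric vector of island sizes in bp.
#' @return List with `n`, `mean_kb`, `min_bp`, `max_bp`.
#' @export
summarize_island_sizes <- function(sizes_bp) {
  stopifnot(is.numeric(sizes_bp), length(sizes_bp) >= 1L)
  list(n = length(sizes_bp),
       mean_kb = mean(sizes_bp) / 1000,
       min_bp = min(sizes_bp),
       max_bp = max(sizes_bp))
}

#' Load a survey size column
#'
#' Reads a one-column (or `size_bp`-column) TSV of island sizes, the input
#' expected by [summarize_island_sizes()] for survey-scale summaries. The
#' package does not bundle any survey: the published 94-island size column
#' lives in journal supplementary material that is not redistributable
#' here, so this loader errors unless the caller supplies a file.
#'
#' @param path TSV path.
#' @return Numeric vector of sizes in bp.
#' @export
load_survey_sizes <- function(path) {
  if (!file.exists(path))
    stop("survey size table not available: ", path,
         " (supply the survey's size column as a TSV)")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  col <- if ("size_bp" %in% names(df)) df$size_bp else df[[1]]
  as.numeric(col)
}
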