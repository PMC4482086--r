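#' Pipeline configuration
#'
#' Central parameter set for the discovery pipeline. Defaults encode the
#' working values used throughout: 21 bp att core (optionally extended),
#' 12 bp exact seed with up to 3 core mismatches, 1 kb maximum
#' integrase-target gap, 200 kb repeat-search window with a 30-60 kb
#' island-size prior band, a 0.3 score-ratio homology screen for
#' integrase candidates and a 0.2 ratio + raw-score-floor-50 surrogate
#' threshold for orthology, 1000 bootstrap replicates and a 1000-window
#' trinucleotide null.
#'
#' @param ... Overrides of the defaults (unknown keys are an error).
#' @return Named list of class `gei_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(core_len = 21L, extend_bp = 0L, seed_len = 12L,
              max_mismatches = 3L, max_gap = 1000L, anchor_radius = 2000L,
              window = 200000L, island_band_lo = 30000L,
              island_band_hi = 60000L, dai_score_ratio = 0.3,
              orth_score_ratio = 0.2, orth_score_floor = 50,
              bootstrap_n = 1000L, tri_null_n = 1000L, seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in names(ov)) cfg[[k]] <- if (is.integer(cfg[[k]]))
    as.integer(ov[[k]]) else as.numeric(ov[[k]])
  num <- unlist(cfg)
  if (any(num <= 0 & !names(num) %in% "extend_bp"))
    stop("all config thresholds must be positive")
  structure(cfg, class = c("gei_config", "list"))
}

#' Read a flat key = value config file
#'
#' @param path Config path; lines of the form `key = value`, `#` comments.
#' @return A `gei_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- utils::type.convert(x[2], as.is = TRUE)
    v
  })
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  do.call(pipeline_config, vals)
}

#' Write a config as a flat key = value file
#'
#' Round-trips losslessly through [read_config()].
#'
#' @param config A `gei_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, "", scientific = FALSE)), path)
  invisible(path)
}

config_header <- function(config) {
  stats::setNames(as.list(vapply(config, format, "", scientific = FALSE)),
                  names(config))
}

#' Scan an annotated replicon for dus-associated islands
#'
#' Runs the discovery chain on one replicon: locate target genes, find the
#' divergently adjacent integrase for each, search the flanking window for
#' the bounding direct-repeat pair, and call island boundaries.
#'
#' @param rep A [replicon()].
#' @param features Feature data frame for that replicon.
#' @param config A [pipeline_config()].
#' @param compute_tri Also compute the trinucleotide atypicality score per
#'   call.
#' @return List of `gei_island` / `gei_nocall` objects (possibly empty,
#'   when no target or no adjacent integrase exists).
#' @export
scan_replicon <- function(rep, features, config = pipeline_config(),
                          compute_tri = FALSE) {
  targets <- find_target_genes(features)
  targets <- targets[targets$replicon_id == rep$id, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(targets))) {
    target <- targets[k, ]
    integ <- find_adjacent_integrase(target, features,
                                     max_gap = config$max_gap)
    if (is.null(integ)) next
    anchor <- five_prime_boundary(target)
    reps <- find_direct_repeats(rep, anchor,
                                anchor_radius = config$anchor_radius,
                                window = config$window,
                                core_len = config$core_len + config$extend_bp,
                                seed_len = config$seed_len,
                                max_mismatches = config$max_mismatches,
                                band = c(config$island_band_lo,
                                         config$island_band_hi))
    out[[length(out) + 1L]] <-
      call_island(rep, target, integ, reps, compute_tri = compute_tri,
                  tri_n_null = config$tri_null_n, tri_seed = config$seed)
  }
  out
}

#' Run a pipeline stage
#'
#' Orchestrates the package's stages as named subcommands writing
#' deterministic outputs into `out_dir`. Every table echoes the effective
#' configuration and seed in its header. Returns status 0 on success and 3
#' when a scan produced no island call ("no-call"); errors propagate as R
#' errors (the command-line wrapper maps them to exit code 1).
#'
#' Subcommands: `simulate` (seeded fixture bundle), `scan` (annotated
#' genome to island-call TSV), `excise` (scan + excision products FASTA +
#' ORF report), `pcr` (template FASTA + primers to amplicon TSV), `logo`
#' (repeat FASTA to information-content TSV), `phylo` (protein FASTA to
#' Newick with bootstrap support), `orthology` (proteome FASTAs to cluster
#' TSV + uniqueness summary).
#'
#' @param subcommand One of `simulate`, `scan`, `excise`, `pcr`, `logo`,
#'   `phylo`, `orthology`.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param genome,features_path Annotated genome inputs (GenBank path, or
#'   FASTA path + feature TSV) for `scan` / `excise`.
#' @param fasta Input FASTA for `pcr` / `logo` / `phylo`; named list of
#'   FASTA paths for `orthology`.
#' @param fwd,rev Primer sequences for `pcr`.
#' @return `list(status = <int>, files = <paths>, result = <object>)`,
#'   invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "scan", "excise", "pcr",
                                        "logo", "phylo", "orthology"),
                         out_dir, config = pipeline_config(),
                         genome = NULL, features_path = NULL, fasta = NULL,
                         fwd = NULL, rev = NULL) {
  subcommand <- match.arg(subcommand)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- config_header(config)

  read_genome_input <- function() {
    fmt <- if (grepl("\\.(gb|gbk|genbank)$", genome)) "genbank"
           else "fasta+features"
    read_annotated_genome(genome, fmt, features_path = features_path)
  }

  if (subcommand == "simulate") {
    wt <- make_wildtype(config$seed)
    truth <- implant_island(wt, config$seed + 1L)
    files <- write_synthetic_bundle(truth, out_dir)
    return(invisible(list(status = 0L, files = files, result = truth)))
  }

  if (subcommand %in% c("scan", "excise")) {
    g <- read_genome_input()
    calls <- list(); products <- list()
    for (rep in g$replicons)
      calls <- c(calls, scan_replicon(rep, g$features, config))
    ok <- Filter(function(x) inherits(x, "gei_island"), calls)
    tsv <- file.path(out_dir, "island_calls.tsv")
    write_island_table(ok, tsv, header = hdr)
    files <- c(islands = tsv)
    if (subcommand == "excise" && length(ok)) {
      for (i in seq_along(ok)) {
        rep <- Find(function(r) r$id == ok[[i]]$replicon_id, g$replicons)
        ex <- reconstruct_excision(rep, ok[[i]], g$features)
        fa <- file.path(out_dir, sprintf("excision_%02d.fasta", i))
        write_fasta_replicons(
          list(replicon(sprintf("%s_circle", rep$id), ex$circle_seq,
                        "circular"),
               replicon(sprintf("%s_restored", rep$id), ex$restored_seq,
                        "linear")), fa)
        orf <- file.path(out_dir, sprintf("orf_report_%02d.tsv", i))
        rep_df <- data.frame(field = names(ex$orf_report),
                             value = unlist(lapply(ex$orf_report, format)))
        utils::write.table(rep_df, orf, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, fa, orf)
        products[[i]] <- ex
      }
    }
    status <- if (length(ok)) 0L else 3L
    return(invisible(list(status = status, files = files,
                          result = list(calls = calls, products = products))))
  }

  if (subcommand == "pcr") {
    reps <- read_fasta_replicons(fasta)
    rows <- do.call(rbind, lapply(reps, function(r) {
      am <- in_silico_pcr(r$seq, fwd, rev, topology = r$topology)
      if (nrow(am)) cbind(template = r$id, am) else NULL
    }))
    if (is.null(rows))
      rows <- data.frame(template = character(0), fwd_pos = integer(0),
                         rev_pos = integer(0), product_len = integer(0))
    tsv <- file.path(out_dir, "amplicons.tsv")
    con <- file(tsv, "w")
    for (k in names(hdr)) writeLines(sprintf("# %s: %s", k, hdr[[k]]), con)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    return(invisible(list(status = 0L, files = c(amplicons = tsv),
                          result = rows)))
  }

  if (subcommand == "logo") {
    set <- Biostrings::readDNAStringSet(fasta)
    logo <- consensus_logo(as.character(set))
    tsv <- file.path(out_dir, "logo.tsv")
    utils::write.table(logo, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(list(status = 0L, files = c(logo = tsv),
                          result = logo)))
  }

  if (subcommand == "phylo") {
    set <- Biostrings::readAAStringSet(fasta)
    seqs <- stats::setNames(as.character(set),
                            vapply(strsplit(names(set), "\\s+"),
                                   `[[`, "", 1L))
    if (length(unique(nchar(seqs))) == 1L) {
      tree <- bootstrap_support(seqs, n_replicates = config$bootstrap_n,
                                seed = config$seed)
    } else {
      tree <- nj_tree(identity_matrix(seqs))
    }
    nwk <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, nwk)
    return(invisible(list(status = 0L, files = c(tree = nwk),
                          result = tree)))
  }

  # orthology
  proteomes <- lapply(fasta, function(p) {
    set <- Biostrings::readAAStringSet(p)
    stats::setNames(as.character(set),
                    vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L))
  })
  orth <- rbh_orthology(proteomes, ratio_threshold = config$orth_score_ratio,
                        score_floor = config$orth_score_floor)
  tsv <- file.path(out_dir, "clusters.tsv")
  write_cluster_table(orth, tsv)
  summ <- file.path(out_dir, "orthology_summary.tsv")
  utils::write.table(
    data.frame(n_genes_total = orth$n_genes_total,
               n_unique = orth$n_unique,
               unique_fraction = orth$unique_fraction,
               n_core_clusters = length(orth$core_clusters)),
    summ, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(status = 0L, files = c(clusters = tsv, summary = summ),
                 result = orth))
}
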