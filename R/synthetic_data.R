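# Seeded generator of wild-type and island-integrated genomes with full
# ground truth. The implanted architecture mirrors the 5'-replacement
# integration mechanism: a 21 bp core inside the target gene's 5' region
# becomes the attL/attR direct-repeat pair bounding the island; the island
# provides a recoded replacement 5' coding segment plus a divergently
# oriented integrase adjacent to the new gene start; a copy of the
# displaced original 5' fragment sits at the island's far boundary; cargo
# is GC-shifted; decoy repeat pairs are planted to stress boundary calling.

base_probs <- function(gc) {
  g <- gc / 100
  c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(names(base_probs(gc)), n, replace = TRUE,
               prob = base_probs(gc)), collapse = "")
}

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code)[code != "*"], code[code != "*"])
}

random_cds <- function(len_bp) {
  stopifnot(len_bp %% 3 == 0, len_bp >= 9)
  n_mid <- len_bp / 3 - 2L
  paste0("ATG",
         paste(sample(setdiff(sense_codons(), "ATG"), n_mid, replace = TRUE),
               collapse = ""),
         "TAA")
}

back_translate <- function(protein) {
  tab <- codon_table()
  paste(vapply(strsplit(protein, "")[[1]],
               function(a) sample(tab[[a]], 1L), ""), collapse = "")
}

#' Generate a wild-type replicon carrying a dusA-like target gene
#'
#' Random background sequence at the requested GC content, one valid
#' target ORF (start codon, no internal stops, stop codon) named dusA on
#' the plus strand away from the origin, and a same-strand neighbour CDS
#' upstream (a transporter-gene stand-in). An in-frame stop codon is
#' planted in the three bases immediately upstream of the target start so
#' the open reading frame recovered across the integration core is exactly
#' the annotated gene.
#'
#' @param seed Integer seed (all randomness flows from it).
#' @param genome_len Replicon length in bp.
#' @param gc Background GC percent.
#' @param target_gene_len Target CDS length in bp (multiple of 3).
#' @return List of class `gei_wildtype`: `replicon`, `features`,
#'   `target_id`, `params`.
#' @export
make_wildtype <- function(seed, genome_len = 200000, gc = 40,
                          target_gene_len = 1035) {
  if (genome_len < 10 * target_gene_len)
    stop("genome_len must be at least 10 x target_gene_len")
  if (target_gene_len %% 3 != 0) stop("target_gene_len must be a multiple of 3")
  set.seed(seed)
  seq <- random_dna(genome_len, gc)
  ws <- as.integer(floor(genome_len * 0.6))
  ws <- ws - (ws %% 3L) + 1L
  we <- ws + target_gene_len - 1L
  dusA_cds <- random_cds(target_gene_len)
  substr(seq, ws, we) <- dusA_cds
  substr(seq, ws - 3L, ws - 1L) <- "TAA"   # in-frame upstream stop guard
  mfs_len <- 1200L
  mfs_end <- ws - 501L
  mfs_start <- mfs_end - mfs_len + 1L
  mfs_cds <- random_cds(mfs_len)
  substr(seq, mfs_start, mfs_end) <- mfs_cds   # same strand as target: tandem
  feats <- rbind(
    gene_features("mfs01", "synthetic_wt", mfs_start, mfs_end, "+", "CDS",
                  "mfsX", "major facilitator superfamily transporter",
                  translate_cds(substr(mfs_cds, 1, mfs_len - 3))),
    gene_features("dusA01", "synthetic_wt", ws, we, "+", "CDS",
                  "dusA", "tRNA-dihydrouridine synthase A",
                  translate_cds(substr(dusA_cds, 1, target_gene_len - 3))))
  structure(list(replicon = replicon("synthetic_wt", seq, "linear"),
                 features = feats,
                 target_id = "dusA01",
                 params = list(seed = seed, genome_len = genome_len, gc = gc,
                               target_gene_len = target_gene_len,
                               target_start = ws, target_end = we)),
            class = "gei_wildtype")
}

recode_synonymous <- function(cds_fragment, forbid_kmer_with = NULL,
                              k = 12L, max_tries = 20L) {
  # Synonymous-codon resampling of an in-frame fragment, keeping the first
  # codon (the start codon); optionally retried until no k-mer is shared
  # with `forbid_kmer_with`, so recoded and original copies cannot cross-
  # seed the repeat search.
  cods <- codons_of(cds_fragment)
  tab <- codon_table()
  code <- Biostrings::GENETIC_CODE
  kmers_of <- function(s) {
    if (nchar(s) < k) return(character(0))
    st <- 1:(nchar(s) - k + 1L)
    substring(s, st, st + k - 1L)
  }
  forbid <- if (is.null(forbid_kmer_with)) character(0)
            else unique(kmers_of(forbid_kmer_with))
  for (try in seq_len(max_tries)) {
    new_cods <- cods
    for (i in seq_along(cods)[-1]) {
      aa <- code[[cods[i]]]
      syn <- tab[[aa]]
      alt <- setdiff(syn, cods[i])
      new_cods[i] <- if (length(alt)) sample(alt, 1L) else cods[i]
    }
    out <- paste(new_cods, collapse = "")
    if (!length(forbid) || !any(kmers_of(out) %in% forbid)) return(out)
  }
  stop("could not recode fragment without sharing a ", k, "-mer")
}

mutate_positions <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Implant an island into a wild-type replicon
#'
#' Inserts an island at a 21 bp core inside the target gene's 5' region,
#' recording complete ground truth. Island layout between the attL and
#' attR cores (ascending coordinates): displaced copy of the original 5'
#' fragment (far boundary) - spacer - GC-shifted cargo - integrase CDS on
#' the minus strand - replacement 5' coding segment ending at attR, in
#' frame with the downstream gene body, so the integrated target gene is a
#' valid ORF encoding the same protein. attR retains the wild-type core
#' (it becomes attB on excision); all configured attL/attR divergence is
#' placed in attL, confined to the outer core positions so the central
#' crossover overlap stays exact. Expected excision products are assembled
#' from the construction records, independently of the boundary-calling
#' code.
#'
#' @param wildtype A `gei_wildtype` from [make_wildtype()].
#' @param seed Integer seed.
#' @param island_len Island size in bp (attL first base to attR last
#'   base); drawn uniformly from `band` when `NULL`.
#' @param band Island-size band to draw from (bp).
#' @param core_len att core length (bp).
#' @param core_mismatches attL/attR Hamming divergence (0-3).
#' @param cargo_gc_shift Cargo GC shift in points above the host GC.
#' @param n_decoys Number of planted decoy repeat pairs.
#' @param core_offset Offset of the core's first base into the target CDS
#'   (bp, multiple of 3).
#' @param integrase_len Integrase CDS length (bp).
#' @param integrase_gap Gap between the integrase 5' end and the new
#'   target-gene start (bp).
#' @return Object of class `gei_truth`; see fields in the source.
#' @export
implant_island <- function(wildtype, seed, island_len = NULL,
                           band = c(30000, 60000), core_len = 21,
                           core_mismatches = 1, cargo_gc_shift = 10,
                           n_decoys = 2, core_offset = 102,
                           integrase_len = 1200, integrase_gap = 150) {
  stopifnot(inherits(wildtype, "gei_wildtype"))
  if (core_mismatches < 0 || core_mismatches > 3)
    stop("core_mismatches must be in 0..3")
  if (core_offset %% 3 != 0) stop("core_offset must be a multiple of 3")
  p <- wildtype$params
  set.seed(seed)
  if (is.null(island_len))
    island_len <- as.integer(round(stats::runif(1, band[1], band[2])))
  if (island_len >= p$genome_len / 2)
    stop("island_len must be below half the genome length")
  wt_seq <- wildtype$replicon$seq
  ws <- p$target_start; we <- p$target_end

  # Core placement: the last codon of the displaced fragment must be
  # third-base degenerate so the replacement segment can end on a codon
  # whose final base differs (see below); slide the core by whole codons
  # until it is, erroring after 10 attempts.
  syn3_options <- function(codon) {
    syn <- codon_table()[[Biostrings::GENETIC_CODE[[codon]]]]
    syn[substr(syn, 1, 2) == substr(codon, 1, 2) &
        substr(syn, 3, 3) != substr(codon, 3, 3)]
  }
  tries <- 0L
  repeat {
    b <- ws + core_offset                     # core first base
    if (length(syn3_options(substr(wt_seq, b - 3L, b - 1L)))) break
    core_offset <- core_offset + 3L
    tries <- tries + 1L
    if (tries >= 10L) stop("no usable core placement found in 10 attempts")
  }
  core <- substr(wt_seq, b, b + core_len - 1L)
  if (grepl("N", core, fixed = TRUE)) stop("core window contains N")

  # attL: wild-type core with divergence confined to outer arm positions
  # 2-4; the central crossover overlap (and attR, the future attB) stays
  # exact, so excision restores the wild type at any configured divergence
  attL <- if (core_mismatches > 0)
    mutate_positions(core, sample(2:4, core_mismatches))
  else core
  attR <- core

  frag <- substr(wt_seq, ws, b - 1L)          # original 5' fragment
  # boundary disambiguation: the base immediately left of attR (last base
  # of the replacement) must differ from the base left of attL (last base
  # of the chromosomal fragment), as unrelated island/chromosome contexts
  # would; enforced by a synonymous third-base swap of the last codon
  last_cod <- substr(frag, nchar(frag) - 2L, nchar(frag))
  for (try in 1:10) {
    replacement <- recode_synonymous(frag, forbid_kmer_with = frag)
    substr(replacement, nchar(replacement) - 2L, nchar(replacement)) <-
      sample(rep(syn3_options(last_cod), 2L), 1L)
    st <- 1:(nchar(frag) - 11L)
    if (!any(substring(replacement, st, st + 11L) %in%
             substring(frag, st, st + 11L))) break
    if (try == 10L) stop("could not recode the replacement segment")
  }

  # integrase protein with the catalytic pentad planted in its C-terminal
  # region, back-translated to a valid CDS
  n_aa <- integrase_len / 3 - 1L
  prot <- paste(sample(strsplit(AA_ALPHABET_STRICT, "")[[1]], n_aa,
                       replace = TRUE), collapse = "")
  pent_at <- floor(n_aa * 0.75) + c(0L, 3L, 6L, 9L, 12L)
  chars <- strsplit(prot, "")[[1]]
  chars[pent_at] <- c("R", "H", "R", "H", "Y")
  prot <- paste(chars, collapse = "")
  int_cds <- paste0("ATG", back_translate(substring(prot, 2L)), "TAA")
  int_segment <- revcomp(int_cds)             # integrase on the minus strand

  # right-flank disambiguation: the three bases immediately right of attL
  # (start of the island interior) are chosen to differ position-by-
  # position from the three bases right of attR (the chromosomal gene
  # body), so no shifted repeat window can tie the planted one
  y_head <- strsplit(substr(wt_seq, b + core_len, b + core_len + 2L), "")[[1]]
  tag3 <- paste(vapply(y_head, function(ch)
    sample(setdiff(c("A", "C", "G", "T"), ch), 1L), ""), collapse = "")

  spacer1_len <- 200L
  interior_fixed <- 3L + nchar(frag) + spacer1_len + nchar(int_segment) +
    integrase_gap + nchar(replacement)
  cargo_len <- island_len - 2L * core_len - interior_fixed
  if (cargo_len < 2000L)
    stop("island_len too small for the fixed island architecture")
  cargo <- random_dna(cargo_len, p$gc + cargo_gc_shift)

  # decoy repeat pairs, planted wholly inside the cargo so excision removes
  # them; 1 outer-position mismatch each, non-bounding by construction
  decoys <- NULL
  if (n_decoys > 0) {
    slots <- floor(cargo_len / (n_decoys * 2L))
    if (slots < 300L) stop("cargo too small for the requested decoys")
    decoys <- do.call(rbind, lapply(seq_len(n_decoys), function(i) {
      d <- random_dna(core_len, 50)
      d2 <- mutate_positions(d, sample(c(1:4, (core_len - 4L):core_len), 1L))
      p1 <- (i * 2L - 2L) * slots + sample.int(slots - core_len - 100L, 1L)
      p2 <- (i * 2L - 1L) * slots + sample.int(slots - core_len - 100L, 1L)
      data.frame(seq1 = d, seq2 = d2, cargo_pos1 = p1, cargo_pos2 = p2,
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(decoys))) {
      substr(cargo, decoys$cargo_pos1[i],
             decoys$cargo_pos1[i] + core_len - 1L) <- decoys$seq1[i]
      substr(cargo, decoys$cargo_pos2[i],
             decoys$cargo_pos2[i] + core_len - 1L) <- decoys$seq2[i]
    }
  }

  spacer1 <- random_dna(spacer1_len, p$gc)
  gap2 <- random_dna(integrase_gap, p$gc)
  substr(gap2, integrase_gap - 2L, integrase_gap) <- "TAA"  # frame guard
  interior <- paste0(tag3, frag, spacer1, cargo, int_segment, gap2, replacement)
  stopifnot(nchar(interior) == island_len - 2L * core_len)

  X <- substr(wt_seq, 1L, b - 1L)
  Y <- substr(wt_seq, b + core_len, p$genome_len)
  int_seq <- paste0(X, attL, interior, attR, Y)
  island_start <- b
  island_end <- b + island_len - 1L
  stopifnot(substr(int_seq, island_start, island_start + core_len - 1L) == attL,
            substr(int_seq, island_end - core_len + 1L, island_end) == attR)

  shift <- island_len - core_len              # displacement of Y coordinates
  attR_start <- island_end - core_len + 1L
  int_start <- b + core_len + 3L + nchar(frag) + spacer1_len + cargo_len
  int_end <- int_start + nchar(int_segment) - 1L
  d1 <- attR_start - nchar(replacement)       # new target-gene start
  target_end_int <- we + shift
  chimeric_cds <- paste0(replacement, attR,
                         substr(wt_seq, b + core_len, we))
  stopifnot(substr(int_seq, d1, target_end_int) == chimeric_cds)

  int_feats <- rbind(
    gene_features("mfs01", "synthetic_int",
                  wildtype$features$start[wildtype$features$id == "mfs01"],
                  wildtype$features$end[wildtype$features$id == "mfs01"],
                  "+", "CDS", "mfsX",
                  "major facilitator superfamily transporter",
                  wildtype$features$translation[wildtype$features$id == "mfs01"]),
    gene_features("int01", "synthetic_int", int_start, int_end, "-", "CDS",
                  "intA", "site-specific tyrosine recombinase",
                  translate_cds(substr(int_cds, 1, nchar(int_cds) - 3))),
    gene_features("dusA01", "synthetic_int", d1, target_end_int, "+", "CDS",
                  "dusA", "tRNA-dihydrouridine synthase A",
                  translate_cds(substr(chimeric_cds, 1,
                                       nchar(chimeric_cds) - 3))))

  expected_circle <- paste0(attL, interior)   # one core copy (attP)
  expected_restored <- paste0(X, core, Y)
  stopifnot(expected_restored == wt_seq)

  structure(list(
    seed = seed,
    wildtype = wildtype,
    integrated = list(replicon = replicon("synthetic_int", int_seq, "linear"),
                      features = int_feats),
    island_start = island_start, island_end = island_end,
    island_len = island_len,
    attL_seq = attL, attR_seq = attR,
    attL_start = island_start, attR_start = attR_start,
    core_len = core_len, core_mismatches = core_mismatches,
    integrase_id = "int01",
    target_id = "dusA01",
    anchor = d1,
    replacement_5prime_len = nchar(replacement),
    displaced_5prime_len = nchar(frag),
    wildtype_cds = substr(wt_seq, ws, we),
    chimeric_cds = chimeric_cds,
    expected_circle = expected_circle,
    expected_restored = expected_restored,
    decoys = decoys),
    class = "gei_truth")
}

#' @export
print.gei_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic truth> seed %d: island %d..%d (%d bp), att divergence %d\n",
    x$seed, x$island_start, x$island_end, x$island_len, x$core_mismatches))
  invisible(x)
}

#' Generate island proteomes with known ortholog families
#'
#' Test bed for reciprocal-best-hit orthology: ancestral proteins are
#' generated and distributed as mutated copies - core families present in
#' every island, shared families in a random subset, and island-unique
#' genes - with true cluster membership recorded.
#'
#' @param seed Integer seed.
#' @param n_islands Number of islands (>= 2).
#' @param n_core Families present in all islands (the integrase stand-in).
#' @param n_shared Families present in a random proper subset of islands.
#' @param n_unique_per_island Island-unique genes per island.
#' @param mutation_rate Per-site substitution probability in `[0, 0.5]`.
#' @param len_range Protein length range (aa).
#' @return List with `proteomes` (named list of named AA vectors),
#'   `truth_clusters` (list of data frames `island`, `gene`), `n_genes`.
#' @export
make_protein_families <- function(seed, n_islands = 4, n_core = 1,
                                  n_shared = 2, n_unique_per_island = 3,
                                  mutation_rate = 0.05,
                                  len_range = c(120, 300)) {
  if (mutation_rate < 0 || mutation_rate > 0.5)
    stop("mutation_rate must be in [0, 0.5]")
  stopifnot(n_islands >= 2, n_core >= 0, n_shared >= 0,
            n_unique_per_island >= 0)
  set.seed(seed)
  aa <- strsplit(AA_ALPHABET_STRICT, "")[[1]]
  rand_prot <- function() paste(
    sample(aa, sample(len_range[1]:len_range[2], 1L), replace = TRUE),
    collapse = "")
  mutate_prot <- function(prot) {
    ch <- strsplit(prot, "")[[1]]
    hit <- stats::runif(length(ch)) < mutation_rate
    ch[hit] <- vapply(ch[hit], function(a) sample(setdiff(aa, a), 1L), "")
    paste(ch, collapse = "")
  }
  islands <- sprintf("island%02d", seq_len(n_islands))
  proteomes <- stats::setNames(vector("list", n_islands), islands)
  for (i in islands) proteomes[[i]] <- character(0)
  truth <- list()
  add_family <- function(fam_id, member_islands) {
    anc <- rand_prot()
    rows <- lapply(member_islands, function(isl) {
      gname <- sprintf("%s_%s", fam_id, isl)
      proteomes[[isl]][[gname]] <<- mutate_prot(anc)
      data.frame(island = isl, gene = gname, stringsAsFactors = FALSE)
    })
    truth[[fam_id]] <<- do.call(rbind, rows)
  }
  pick1 <- function(x) x[sample.int(length(x), 1L)]   # no 1:n expansion
  for (k in seq_len(n_core)) add_family(sprintf("core%d", k), islands)
  for (k in seq_len(n_shared)) {
    sz <- if (n_islands > 2) pick1(2:(n_islands - 1L)) else 2L
    add_family(sprintf("shared%d", k), sort(sample(islands, sz)))
  }
  for (isl in islands) {
    for (k in seq_len(n_unique_per_island))
      add_family(sprintf("uniq_%s_%d", isl, k), isl)
  }
  proteomes <- lapply(proteomes, unlist)
  list(proteomes = proteomes, truth_clusters = unname(truth),
       n_genes = sum(vapply(proteomes, length, 0L)))
}

#' Write a synthetic fixture bundle
#'
#' Emits the wild-type and integrated replicons as FASTA, the integrated
#' replicon as a GenBank flat file, the feature tables as TSV, and the
#' ground truth as JSON. The generator seed is embedded in every header.
#'
#' @param truth A `gei_truth` from [implant_island()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_synthetic_bundle <- function(truth, dir) {
  stopifnot(inherits(truth, "gei_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_tag <- sprintf("seed=%d", truth$seed)
  paths <- c(
    wildtype_fasta = file.path(dir, "wildtype.fasta"),
    integrated_fasta = file.path(dir, "integrated.fasta"),
    integrated_gb = file.path(dir, "integrated.gb"),
    wildtype_features = file.path(dir, "wildtype_features.tsv"),
    integrated_features = file.path(dir, "integrated_features.tsv"),
    truth_json = file.path(dir, "truth.json"))
  write_fasta_replicons(truth$wildtype$replicon, paths["wildtype_fasta"],
                        extra = stats::setNames(seed_tag,
                                                truth$wildtype$replicon$id))
  write_fasta_replicons(truth$integrated$replicon, paths["integrated_fasta"],
                        extra = stats::setNames(seed_tag,
                                                truth$integrated$replicon$id))
  write_genbank(truth$integrated$replicon, truth$integrated$features,
                paths["integrated_gb"], comment = seed_tag)
  write_feature_table(truth$wildtype$features, paths["wildtype_features"],
                      header = list(seed = truth$seed))
  write_feature_table(truth$integrated$features, paths["integrated_features"],
                      header = list(seed = truth$seed))
  truth_min <- truth[c("seed", "island_start", "island_end", "island_len",
                       "attL_seq", "attR_seq", "attL_start", "attR_start",
                       "core_len", "core_mismatches", "anchor",
                       "replacement_5prime_len", "displaced_5prime_len",
                       "wildtype_cds", "expected_circle", "expected_restored")]
  jsonlite::write_json(truth_min, paths["truth_json"], auto_unbox = TRUE,
                       digits = NA)
  paths
}
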