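#' Find candidate island target genes
#'
#' Targets are the tRNA-dihydrouridine synthase genes (dusA and its dusB /
#' dusC paralogues): matched either by exact (case-insensitive) gene name or
#' by a configured synonym phrase appearing verbatim in the product text.
#'
#' @param features Feature data frame ([gene_features()]).
#' @param names Gene names matched exactly (case-insensitive).
#' @param synonyms Product phrases matched as exact substrings
#'   (case-insensitive).
#' @return The matching rows, in ascending coordinate order.
#' @export
find_target_genes <- function(features,
                              names = c("dusA", "dusB", "dusC"),
                              synonyms = "tRNA-dihydrouridine synthase") {
  if (!nrow(features)) return(features)
  by_name <- tolower(features$name) %in% tolower(names)
  by_prod <- rep(FALSE, nrow(features))
  for (syn in synonyms)
    by_prod <- by_prod | grepl(syn, features$product, fixed = FALSE,
                               ignore.case = TRUE)
  out <- features[by_name | by_prod, , drop = FALSE]
  out[order(out$replicon_id, out$start), , drop = FALSE]
}

five_prime_boundary <- function(f) if (f$strand == "+") f$start else f$end

classify_geometry <- function(target, cand) {
  # "divergent": opposite strands, 5' ends facing each other across the gap;
  # "convergent": opposite strands, 3' ends facing; "tandem": same strand.
  if (target$strand == cand$strand) return("tandem")
  cand_is_left <- cand$end < target$start
  left <- if (cand_is_left) cand else target
  right <- if (cand_is_left) target else cand
  # left gene's 5' boundary faces the gap iff it is on "-"; right's iff "+"
  if (left$strand == "-" && right$strand == "+") "divergent" else "convergent"
}

#' Find the integrase gene adjoining a target gene
#'
#' Implements the association criterion: the integrase is the nearest CDS
#' whose 5' end adjoins the 5' end of the target gene, i.e. the two genes
#' are divergently oriented with their start-codon-proximal boundaries
#' separated by at most `max_gap`. A permissive mode accepting any
#' orientation is available for surveys.
#'
#' @param target One feature row (the dus gene).
#' @param features Feature data frame sharing the target's replicon.
#' @param max_gap Maximum gap in bp between the facing boundaries.
#' @param geometry `"divergent"` (default association criterion) or
#'   `"any"`.
#' @param motif_window_frac Passed to [motif_check()].
#' @return A `gei_integrase_candidate` (list with `feature`, `target`,
#'   `gap_bp`, `geometry`, `association_class`, `motif`) or `NULL` when no
#'   CDS qualifies. Multiple equally-near candidates raise an error.
#' @export
find_adjacent_integrase <- function(target, features, max_gap = 1000,
                                    geometry = c("divergent", "any"),
                                    motif_window_frac = 0.6) {
  geometry <- match.arg(geometry)
  cand <- features[features$replicon_id == target$replicon_id &
                   features$kind == "CDS" &
                   features$id != target$id, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    f <- cand[k, ]
    if (f$start <= target$end && f$end >= target$start) return(NULL) # overlap
    gap <- if (f$end < target$start) target$start - f$end - 1L
           else f$start - target$end - 1L
    geo <- classify_geometry(target, f)
    if (gap > max_gap) return(NULL)
    if (geometry == "divergent") {
      if (geo != "divergent") return(NULL)
      # the facing boundaries must be the 5' ends of both genes
      t5 <- five_prime_boundary(target); c5 <- five_prime_boundary(f)
      inner <- sort(c(if (f$end < target$start) c(f$end, target$start)
                      else c(target$end, f$start)))
      if (!(t5 %in% inner && c5 %in% inner)) return(NULL)
    }
    list(row = k, gap = gap, geo = geo)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  gaps <- vapply(rows, `[[`, 0, "gap")
  best <- which(gaps == min(gaps))
  if (length(best) > 1L) {
    ids <- vapply(best, function(i) cand$id[rows[[i]]$row], "")
    stop("ambiguous integrase association: equally near candidates ",
         paste(ids, collapse = ", "))
  }
  hit <- rows[[best]]
  f <- cand[hit$row, ]
  motif <- if (!is.na(f$translation))
    motif_check(f$translation, window_frac = motif_window_frac)
  else list(pass = NA, positions = NULL)
  assoc <- if (tolower(target$name) %in% c("dusa", "dusb", "dusc"))
    tolower(target$name) else "non-dus"
  assoc <- c(dusa = "dusA", dusb = "dusB", dusc = "dusC")[assoc]
  if (is.na(assoc)) assoc <- "non-dus"
  structure(list(feature = f, target = target, gap_bp = hit$gap,
                 geometry = hit$geo, association_class = unname(assoc),
                 motif = motif),
            class = "gei_integrase_candidate")
}

#' @export
print.gei_integrase_candidate <- function(x, ...) {
  cat(sprintf(
    "<integrase candidate> %s (%d..%d %s) %s to %s (%s), gap %d bp, motif %s\n",
    x$feature$id, x$feature$start, x$feature$end, x$feature$strand,
    x$geometry, x$target$name, x$association_class, x$gap_bp,
    if (isTRUE(x$motif$pass)) "pass" else if (isFALSE(x$motif$pass)) "fail"
    else "n/a"))
  invisible(x)
}

#' Tyrosine-recombinase catalytic motif scan
#'
#' Screens a protein for the ordered catalytic pentad R...H...R...H...Y
#' within its C-terminal catalytic region (by default the C-terminal 60% of
#' the sequence). This is a cheap character screen, not proof of family
#' membership.
#'
#' @param protein Amino-acid string.
#' @param window_frac Fraction of the protein (from the C terminus) that
#'   must contain the whole pentad.
#' @return List with `pass` (logical) and `positions` (integer vector of
#'   the five residue positions, 1-based on the full protein) or `NULL`.
#' @examples
#' motif_check("MRAHARAHAYA", window_frac = 1)$positions
#' @export
motif_check <- function(protein, window_frac = 0.6) {
  protein <- check_protein(protein)
  L <- nchar(protein)
  win_start <- L - floor(L * window_frac) + 1L
  chars <- strsplit(protein, "")[[1]]
  pent <- c("R", "H", "R", "H", "Y")
  pos <- integer(0); at <- win_start
  for (res in pent) {
    hit <- which(chars[at:L] == res)
    if (!length(hit)) return(list(pass = FALSE, positions = NULL))
    p <- at + hit[1] - 1L
    pos <- c(pos, p); at <- p + 1L
  }
  list(pass = TRUE, positions = pos)
}

#' Local-similarity homology screen
#'
#' Surrogate for a database homology search: scores the query against a
#' user-supplied reference panel by local alignment (BLOSUM62, gap open 11 /
#' extend 1) and reports the best score as a fraction of that reference's
#' self-score. A shuffled (non-homologous) protein scores far below the
#' default threshold.
#'
#' @param protein Query amino-acid string.
#' @param references Named character vector of reference proteins.
#' @param threshold Minimum score ratio for a pass.
#' @return List with `best_reference`, `score_ratio`, `pass` and the raw
#'   `score`.
#' @export
homology_screen <- function(protein, references, threshold = 0.3) {
  if (length(references) < 1L) stop("at least one reference is required")
  protein <- check_protein(protein, "query")
  refs <- vapply(references, check_protein, "", what = "reference")
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    names(refs) <- sprintf("ref%d", seq_along(refs))
  sc <- local_scores(protein, refs)
  selfs <- vapply(refs, self_score, 0)
  ratios <- sc / selfs
  best <- which.max(ratios)     # ties resolved first-by-input-order
  list(best_reference = names(refs)[best],
       score = sc[best],
       score_ratio = unname(ratios[best]),
       pass = unname(ratios[best] >= threshold))
}

#' Write a candidate table
#'
#' Serialises integrase candidates to the TSV surface used by the pipeline.
#'
#' @param candidates List of `gei_integrase_candidate` objects.
#' @param path Output path.
#' @param score_ratios Optional numeric vector (one per candidate) from
#'   [homology_screen()].
#' @export
write_candidate_table <- function(candidates, path, score_ratios = NULL) {
  df <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    x <- candidates[[i]]
    data.frame(replicon_id = x$target$replicon_id,
               target_name = x$target$name,
               target_coords = sprintf("%d..%d", x$target$start, x$target$end),
               integrase_coords = sprintf("%d..%d", x$feature$start,
                                          x$feature$end),
               gap_bp = x$gap_bp, geometry = x$geometry,
               association_class = x$association_class,
               motif_pass = isTRUE(x$motif$pass),
               score_ratio = if (is.null(score_ratios)) NA_real_
                             else score_ratios[i],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
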