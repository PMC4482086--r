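# Internal alignment and translation helpers shared by the detection and
# comparative layers. All protein alignments use BLOSUM62 with affine gaps
# (open 11, extend 1), the conventional BLAST-like parameterisation.

.gei_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.gei_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .gei_env$BLOSUM62 <- e$BLOSUM62
  }
  .gei_env$BLOSUM62
}

AA_ALPHABET_STRICT <- "ACDEFGHIKLMNPQRSTVWY"

check_protein <- function(p, what = "protein") {
  if (!is.character(p) || length(p) != 1L || !nzchar(p))
    stop(what, " must be a non-empty amino-acid string")
  p <- toupper(p)
  if (grepl(sprintf("[^%s]", AA_ALPHABET_STRICT), p))
    stop(what, " contains non-amino-acid characters: ",
         paste(unique(strsplit(gsub(sprintf("[%s]", AA_ALPHABET_STRICT), "", p),
                               "")[[1]]), collapse = ", "))
  p
}

# Local (Smith-Waterman) alignment score of one query against a vector of
# references; vectorised over the references.
local_scores <- function(query, refs) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(refs),
    subject = Biostrings::AAString(query),
    substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, type = "local", scoreOnly = TRUE)
  as.numeric(pa)
}

self_score <- function(p) local_scores(p, p)

# Global (Needleman-Wunsch) alignment of a single pair; returns the two
# aligned strings (with "-" gaps) and the score.
global_align <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# Global DNA alignment percent identity (simple +1/-1 scoring, affine gaps);
# used for restored-gene validation.
dna_global_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    type = "global")
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  100 * sum(x == y & x != "-") / length(x)
}

# Bacterial translation (code table 11; same codon table as the standard
# code, start-codon handling is done by callers). Plain table lookup -
# kept fast because the generator translates every emitted CDS.
translate_cds <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  cods <- codons_of(toupper(dna))
  aa <- unname(code[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_of <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Quick ORF sanity report for a CDS string (expected to include the stop).
orf_report <- function(cds) {
  cods <- codons_of(cds)
  internal <- cods[-length(cods)]
  list(has_start_codon = cods[1] %in% START_CODONS,
       no_internal_stop = !any(internal %in% STOP_CODONS),
       ends_with_stop = cods[length(cods)] %in% STOP_CODONS,
       length_aa = length(internal))
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance requires equal lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
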