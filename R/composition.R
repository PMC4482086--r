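#' GC content
#'
#' Percent G+C over counted bases. N is excluded from both numerator and
#' denominator; the value is reported to one decimal, the precision used in
#' island coordinate tables.
#'
#' @param seq DNA string.
#' @return GC percentage (one decimal).
#' @examples
#' gc_percent("AANGTG")  # 40.0: N excluded, 2 GC over 5 counted bases
#' @export
gc_percent <- function(seq) {
  if (!nzchar(seq)) stop("gc_percent of an empty sequence is undefined")
  seq <- toupper(seq)
  counts <- table(factor(strsplit(seq, "")[[1]],
                         levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stop("gc_percent undefined: no A/C/G/T bases")
  round(100 * sum(counts[c("G", "C")]) / denom, 1)
}

ALL_TRINUCS <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"), paste0),
                               c("A", "C", "G", "T"), paste0))

tri_index <- function(seq) {
  # 1-based index into the 64 trinucleotides for every overlapping window
  # on the given strand; NA where the window contains a non-ACGT character.
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- code[strsplit(seq, "")[[1]]]
  n <- length(v)
  if (n < 3L) return(integer(0))
  v[is.na(v)] <- NA_integer_
  idx <- v[1:(n - 2L)] * 16L + v[2:(n - 1L)] * 4L + v[3:n] + 1L
  idx
}

#' Overlapping trinucleotide profile
#'
#' Counts every overlapping 3-mer on the given strand (step 1). Circular
#' sequences add the two origin-spanning windows. Windows containing N are
#' skipped; a profile with no valid window is flagged empty.
#'
#' @param seq DNA string, length >= 3.
#' @param circular Include the two wrap-around windows.
#' @return List of class `gei_triprofile`: `counts` (named 64-vector),
#'   `freqs`, `n_windows`, `empty`.
#' @export
tri_profile <- function(seq, circular = FALSE) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("tri_profile requires length >= 3")
  if (circular) seq <- paste0(seq, substr(seq, 1L, 2L))
  idx <- tri_index(seq)
  idx <- idx[!is.na(idx)]
  counts <- tabulate(idx, nbins = 64L)
  names(counts) <- ALL_TRINUCS
  n <- sum(counts)
  structure(list(counts = counts,
                 freqs = if (n > 0) counts / n else counts * NA_real_,
                 n_windows = n, empty = n == 0L),
            class = "gei_triprofile")
}

#' Trinucleotide atypicality score against a host background
#'
#' Empirical-null z-score of a region's trinucleotide composition: `n_null`
#' windows of the region's length are drawn uniformly from the host
#' replicon (seeded), per-3-mer means and standard deviations of the null
#' frequencies are computed, and the region's frequencies are standardised
#' against them. The score is the mean absolute z over the 64 components;
#' laterally acquired regions with atypical composition score high. Only
#' the given strand is counted. No significance threshold is imposed -
#' ranking is left to the caller.
#'
#' @param island A `gei_triprofile` for the region of interest.
#' @param host A [replicon()] providing the background.
#' @param island_len Region length in bp (null window size).
#' @param n_null Number of null windows (>= 2).
#' @param seed Integer seed for the null draw.
#' @return List with `z` (named 64-vector) and `score` (mean |z|).
#' @export
tri_zscore <- function(island, host, island_len, n_null = 1000, seed = 1L) {
  stopifnot(inherits(island, "gei_triprofile"), inherits(host, "gei_replicon"))
  if (island$empty) stop("island profile is empty (all windows contained N)")
  if (n_null < 2L) stop("n_null must be >= 2 (SD undefined otherwise)")
  if (host$length < 2L * island_len)
    stop("host replicon must be at least twice the island length")
  host_idx <- tri_index(host$seq)
  max_start <- host$length - island_len + 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- sample.int(max_start, n_null, replace = TRUE)
  nw <- island_len - 2L
  freqs <- matrix(0, nrow = n_null, ncol = 64L)
  for (i in seq_len(n_null)) {
    idx <- host_idx[starts[i]:(starts[i] + nw - 1L)]
    idx <- idx[!is.na(idx)]
    cnt <- tabulate(idx, nbins = 64L)
    freqs[i, ] <- if (sum(cnt) > 0) cnt / sum(cnt) else NA_real_
  }
  mu <- colMeans(freqs, na.rm = TRUE)
  sdv <- apply(freqs, 2, stats::sd, na.rm = TRUE)
  sdv <- pmax(sdv, 1e-6)
  z <- (island$freqs - mu) / sdv
  names(z) <- ALL_TRINUCS
  list(z = z, score = mean(abs(z)))
}

#' Write a trinucleotide profile (and optional z-vector) as TSV
#'
#' @param profile A `gei_triprofile`.
#' @param path Output path.
#' @param z Optional named z-vector from [tri_zscore()].
#' @export
write_tri_table <- function(profile, path, z = NULL) {
  df <- data.frame(trinucleotide = ALL_TRINUCS,
                   count = as.integer(profile$counts),
                   freq = as.numeric(profile$freqs))
  if (!is.null(z)) df$z <- as.numeric(z)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
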