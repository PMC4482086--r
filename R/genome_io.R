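#' Create a replicon
#'
#' A replicon is a named DNA sequence with explicit topology. All coordinates
#' in the package are 1-based and fully inclusive, matching the convention of
#' published island coordinate tables (size = end - start + 1).
#'
#' @param id Replicon identifier.
#' @param seq DNA string over A, C, G, T, N (case-insensitive; normalised to
#'   upper case).
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `gei_replicon` with fields `id`, `seq`,
#'   `topology` and `length`.
#' @examples
#' rep <- replicon("chr", "acgtt", "circular")
#' rep$length
#' @export
replicon <- function(id, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("replicon sequence must have length >= 1")
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
    stop("replicon sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, seq = seq, topology = topology,
                 length = nchar(seq)),
            class = "gei_replicon")
}

#' @export
print.gei_replicon <- function(x, ...) {
  cat(sprintf("<gei_replicon> %s: %d bp, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Build a gene feature table
#'
#' Features are stored in a plain data frame, one row per feature, with
#' 1-based inclusive coordinates. Wrap-around features are never stored;
#' extraction handles the origin for circular replicons.
#'
#' @param id Feature identifiers.
#' @param replicon_id Replicon each feature lives on.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param kind `"CDS"`, `"tRNA"` or `"other"`.
#' @param name Gene name (e.g. `"dusA"`); may be `""`.
#' @param product Product description; may be `""`.
#' @param translation Amino-acid string for CDS features, or `NA`.
#' @return A `data.frame` with the nine columns above.
#' @export
gene_features <- function(id, replicon_id, start, end, strand,
                          kind = "CDS", name = "", product = "",
                          translation = NA_character_) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   replicon_id = as.character(replicon_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   kind = rep_len(as.character(kind), n),
                   name = rep_len(as.character(name), n),
                   product = rep_len(as.character(product), n),
                   translation = rep_len(as.character(translation), n),
                   stringsAsFactors = FALSE)
  if (any(df$start < 1L) || any(df$start > df$end))
    stop("feature coordinates must satisfy 1 <= start <= end")
  if (!all(df$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  df
}

empty_features <- function() {
  gene_features(character(), character(), integer(), integer(), character())
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A, C, G, T, N).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a subsequence from a replicon
#'
#' Coordinates are 1-based inclusive. On circular replicons `start > end`
#' wraps through the origin; on linear replicons that is a topology error.
#' `strand = "-"` returns the reverse complement of the extracted span.
#'
#' @param rep A [replicon()].
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return DNA string.
#' @examples
#' subsequence(replicon("r", "ACGTT", "circular"), 4, 2)  # "TTAC"
#' @export
subsequence <- function(rep, start, end, strand = "+") {
  stopifnot(inherits(rep, "gei_replicon"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < 1L || start > rep$length || end > rep$length)
    stop(sprintf("coordinate out of range [1, %d]: start=%d end=%d",
                 rep$length, start, end))
  if (start <= end) {
    s <- substr(rep$seq, start, end)
  } else {
    if (rep$topology != "circular")
      stop("wrap-around span requested on a linear replicon")
    s <- paste0(substr(rep$seq, start, rep$length), substr(rep$seq, 1L, end))
  }
  if (strand == "-") s <- revcomp(s)
  s
}

#' Inclusive span size
#'
#' Size of the inclusive coordinate span `[start, end]`, i.e.
#' `end - start + 1`. Wrap-around spans must be canonicalised by the caller
#' before use.
#'
#' @param start,end 1-based inclusive coordinates with `start <= end`.
#' @return Integer span size in bp.
#' @examples
#' span_size(595655, 642997)  # 47343
#' @export
span_size <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start > end))
    stop("span_size requires start <= end (canonicalize wrap-around first)")
  as.integer(end - start + 1)
}

## ---- FASTA ----

#' Read a FASTA file as replicons
#'
#' @param path FASTA file path.
#' @param topology Topology assigned to every record, or per-record when a
#'   header contains the token `circular`.
#' @return List of [replicon()] objects.
#' @export
read_fasta_replicons <- function(path, topology = "linear") {
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    topo <- if (grepl("\\bcircular\\b", headers[i])) "circular" else topology
    id <- strsplit(headers[i], "\\s+")[[1]][1]
    replicon(id, as.character(set[[i]]), topo)
  })
}

#' Write replicons to FASTA
#'
#' Circular records are flagged with the token `circular` in the header.
#'
#' @param reps A [replicon()] or list of them.
#' @param path Output path.
#' @param extra Optional named character vector of extra header text per
#'   record.
#' @export
write_fasta_replicons <- function(reps, path, extra = NULL) {
  if (inherits(reps, "gei_replicon")) reps <- list(reps)
  seqs <- Biostrings::DNAStringSet(vapply(reps, `[[`, "", "seq"))
  names(seqs) <- vapply(reps, function(r) {
    h <- r$id
    if (r$topology == "circular") h <- paste(h, "circular")
    if (!is.null(extra) && r$id %in% names(extra))
      h <- paste(h, extra[[r$id]])
    h
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

## ---- feature table TSV ----

#' Read a tab-separated feature table
#'
#' Columns: `replicon_id`, `start`, `end`, `strand`, `kind`, `name`,
#' `product` and optionally `id` and `translation`. Lines starting with `#`
#' are ignored.
#'
#' @param path TSV path.
#' @return Feature data frame as from [gene_features()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("replicon_id", "start", "end", "strand", "kind", "name", "product")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$id)) df$id <- sprintf("feat%04d", seq_len(nrow(df)))
  if (is.null(df$translation)) df$translation <- NA_character_
  df$translation[df$translation %in% c("", "NA")] <- NA_character_
  gene_features(df$id, df$replicon_id, df$start, df$end, df$strand,
                df$kind, df$name, df$product, df$translation)
}

#' Write a feature table to TSV
#'
#' @param features Feature data frame.
#' @param path Output path.
#' @param header Optional named list echoed as `# key: value` comment lines.
#' @export
write_feature_table <- function(features, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  utils::write.table(features, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- GenBank flat file (minimal dialect) ----

parse_gb_location <- function(loc, lineno) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("join|order", loc))
    stop(sprintf("compound location unsupported (line %d): %s", lineno, loc))
  m <- regmatches(loc, regexec("^complement\\((\\d+)\\.\\.(\\d+)\\)$", loc))[[1]]
  if (length(m) == 3L) {
    strand <- "-"
  } else {
    m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
    if (length(m) != 3L) {
      m1 <- regmatches(loc, regexec("^(\\d+)$", loc))[[1]]
      if (length(m1) == 2L) m <- c(m1[1], m1[2], m1[2])
      else stop(sprintf("unparseable location (line %d): %s", lineno, loc))
    }
  }
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

#' Read a GenBank flat file
#'
#' Minimal reader for the subset of the format the package emits and
#' consumes: `LOCUS` (length, linear/circular), `FEATURES` with simple or
#' `complement()` locations and the `/gene`, `/product`, `/translation`,
#' `/locus_tag` qualifiers, and `ORIGIN`. Compound (`join`/`order`)
#' locations are rejected explicitly rather than flattened.
#'
#' @param path GenBank file path.
#' @return `list(replicons = <list of replicon>, features = <data frame>)`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  replicons <- list(); features_list <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (!grepl("^LOCUS", lines[i])) { i <- i + 1L; next }
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    rec_id <- toks[2]
    topo <- if ("circular" %in% toks) "circular" else "linear"
    feats <- list()
    i <- i + 1L
    # skip to FEATURES
    while (i <= n && !grepl("^FEATURES", lines[i]) &&
           !grepl("^ORIGIN", lines[i])) i <- i + 1L
    if (i <= n && grepl("^FEATURES", lines[i])) {
      i <- i + 1L
      cur <- NULL
      flush_feat <- function(cur) {
        if (is.null(cur) || cur$key %in% c("source")) return(NULL)
        kind <- if (cur$key %in% c("CDS", "tRNA")) cur$key else "other"
        gene_features(cur$locus_tag %||% sprintf("%s_f%03d", rec_id,
                                                 length(feats) + 1L),
                      rec_id, cur$start, cur$end, cur$strand, kind,
                      cur$gene %||% "", cur$product %||% "",
                      cur$translation %||% NA_character_)
      }
      while (i <= n && !grepl("^ORIGIN", lines[i]) && !grepl("^//", lines[i])) {
        line <- lines[i]
        if (grepl("^     \\S", line)) {            # new feature key
          f <- flush_feat(cur); if (!is.null(f)) feats[[length(feats) + 1L]] <- f
          parts <- strsplit(trimws(line), "\\s+")[[1]]
          loc <- parse_gb_location(parts[2], i)
          cur <- list(key = parts[1], start = loc$start, end = loc$end,
                      strand = loc$strand)
        } else if (grepl("^\\s+/", line)) {        # qualifier
          q <- sub("^\\s+/", "", line)
          key <- sub("=.*$", "", q)
          val <- if (grepl("=", q)) sub("^[^=]+=", "", q) else "TRUE"
          val <- gsub("\"", "", val)
          # multiline qualifier continuation: indented lines that are
          # neither a new qualifier nor a new feature key
          is_cont <- function(l) {
            tl <- trimws(l)
            nzchar(tl) && !startsWith(tl, "/") &&
              !grepl("^     \\S", l) && !grepl("^(ORIGIN|//)", l) &&
              grepl("^\\s", l)
          }
          while (i + 1L <= n && is_cont(lines[i + 1L])) {
            i <- i + 1L
            val <- paste0(val, gsub("\"", "", trimws(lines[i])))
          }
          cur[[key]] <- val
        }
        i <- i + 1L
      }
      f <- flush_feat(cur); if (!is.null(f)) feats[[length(feats) + 1L]] <- f
    }
    # ORIGIN block
    seq <- ""
    if (i <= n && grepl("^ORIGIN", lines[i])) {
      i <- i + 1L
      chunks <- character()
      while (i <= n && !grepl("^//", lines[i])) {
        chunks[length(chunks) + 1L] <- gsub("[^A-Za-z]", "", lines[i])
        i <- i + 1L
      }
      seq <- paste(chunks, collapse = "")
    }
    if (!nzchar(seq))
      stop("GenBank record ", rec_id, " has no ORIGIN sequence")
    replicons[[length(replicons) + 1L]] <- replicon(rec_id, seq, topo)
    features_list[[length(features_list) + 1L]] <-
      if (length(feats)) do.call(rbind, feats) else empty_features()
    i <- i + 1L
  }
  if (!length(replicons)) stop("no LOCUS record found in ", path)
  list(replicons = replicons,
       features = do.call(rbind, features_list))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a GenBank flat file
#'
#' Emits the same minimal dialect [read_genbank()] consumes.
#'
#' @param rep A [replicon()].
#' @param features Feature data frame for that replicon.
#' @param path Output path.
#' @param comment Optional COMMENT line (e.g. generator seed).
#' @export
write_genbank <- function(rep, features, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT %s",
                     rep$id, rep$length, rep$topology,
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", rep$id), con)
  if (!is.null(comment)) writeLines(sprintf("COMMENT     %s", comment), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", rep$length), con)
  feats <- features[features$replicon_id == rep$id, , drop = FALSE]
  wrap_qual <- function(txt) {
    # wrap long qualifier values at 58 chars, GenBank-style continuation
    out <- character()
    while (nchar(txt) > 58L) {
      out <- c(out, substr(txt, 1L, 58L)); txt <- substr(txt, 59L, nchar(txt))
    }
    c(out, txt)
  }
  for (k in seq_len(nrow(feats))) {
    f <- feats[k, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (f$kind %in% c("CDS", "tRNA")) f$kind else "misc_feature"
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", f$id), con)
    if (nzchar(f$name))
      writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (nzchar(f$product))
      writeLines(sprintf("                     /product=\"%s\"", f$product), con)
    if (!is.na(f$translation)) {
      tl <- wrap_qual(sprintf("/translation=\"%s\"", f$translation))
      writeLines(paste0("                     ", tl), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, rep$length, by = 60L)
  for (p in pos) {
    chunk <- substr(rep$seq, p, min(p + 59L, rep$length))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read an annotated genome
#'
#' Front door for annotated input: either a GenBank flat file or a FASTA
#' file plus a tab-separated feature table.
#'
#' @param path GenBank or FASTA path.
#' @param format `"genbank"` or `"fasta+features"`.
#' @param features_path Feature-table path (required for
#'   `"fasta+features"`).
#' @return `list(replicons = <list>, features = <data frame>)`.
#' @export
read_annotated_genome <- function(path,
                                  format = c("genbank", "fasta+features"),
                                  features_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genbank") return(read_genbank(path))
  if (is.null(features_path))
    stop("format 'fasta+features' requires features_path")
  list(replicons = read_fasta_replicons(path),
       features = read_feature_table(features_path))
}
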