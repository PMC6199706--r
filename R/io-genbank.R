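# Minimal GenBank flatfile reader/writer.
#
# Scope: single-locus files with an ORIGIN block and CDS features whose
# locations are `a..b`, `complement(a..b)` or `join(...)` thereof (a joined
# location is stored as its spanning interval). This covers prophage-region
# records and the fixtures the test suite writes; it is not a general EMBL/
# GenBank round-tripper.

#' Read a single-locus GenBank flatfile
#'
#' GenBank 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. CDS `/translation` qualifiers are kept;
#' when absent the translation can be derived later with the bacterial
#' genetic code (table 11). A CDS without a parseable location is skipped
#' with a warning; a missing ORIGIN block is an error.
#'
#' @param path GenBank flatfile.
#' @return A [region_record()] with one [cds_feature()] per CDS.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else
    tools::file_path_sans_ext(basename(path))

  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop(sprintf("%s: no ORIGIN block", path))
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > oi[1]][1] else length(lines) + 1L
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[(oi[1] + 1L):(end_i - 1L)]
  sequence <- paste(gsub("[^A-Za-z]", "", seq_lines), collapse = "")
  if (!nzchar(sequence)) stop(sprintf("%s: empty ORIGIN block", path))

  feats <- parse_genbank_cds(lines[seq_len(oi[1] - 1L)], nchar(sequence), path)
  region_record(id, sequence, features = feats, source = path)
}

parse_genbank_cds <- function(lines, seq_len_bp, path) {
  fi <- grep("^FEATURES", lines)
  if (!length(fi)) return(list())
  lines <- lines[(fi[1] + 1L):length(lines)]
  # feature starts: exactly 5 leading spaces then a key
  key_i <- grep("^ {5}\\S", lines)
  if (!length(key_i)) return(list())
  keys <- sub("^ {5}(\\S+).*$", "\\1", lines[key_i])
  bounds <- c(key_i, length(lines) + 1L)
  feats <- list()
  for (j in seq_along(key_i)) {
    if (keys[j] != "CDS") next
    block <- lines[key_i[j]:(bounds[j + 1L] - 1L)]
    feat <- parse_cds_block(block, seq_len_bp)
    if (is.null(feat)) {
      warning(sprintf("%s: CDS without parseable location skipped", path),
              call. = FALSE)
    } else feats[[length(feats) + 1L]] <- feat
  }
  feats
}

parse_cds_block <- function(block, seq_len_bp) {
  # location may continue over lines until the first qualifier (/...)
  body <- sub("^ {5}CDS\\s*", "", block[1])
  k <- 2L
  while (k <= length(block) && !grepl("^\\s*/", block[k])) {
    body <- paste0(body, trimws(block[k])); k <- k + 1L
  }
  loc <- parse_gb_location(body)
  if (is.null(loc)) return(NULL)
  quals <- paste(trimws(block[k:length(block)]), collapse = "\n")
  product <- gb_qualifier(quals, "product")
  translation <- gb_qualifier(quals, "translation")
  if (!is.null(translation)) translation <- gsub("[\n ]", "", translation)
  if (loc$end > seq_len_bp) return(NULL)
  tr <- translation
  if (!is.null(tr)) {
    want <- (loc$end - loc$start + 1L) %/% 3L
    if (!nchar(tr) %in% c(want, want - 1L)) tr <- NULL  # joined CDS etc.
  }
  cds_feature(loc$start - 1L, loc$end, loc$strand,
              product = product %||% "", translation = tr)
}

parse_gb_location <- function(x) {
  x <- gsub("\\s", "", x)
  strand <- "+"
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) x <- sub("^join\\((.*)\\)$", "\\1", x)
  nums <- regmatches(x, gregexpr("[0-9]+", x))[[1]]
  if (length(nums) < 2L) return(NULL)
  nums <- as.integer(nums)
  list(start = min(nums), end = max(nums), strand = strand)
}

gb_qualifier <- function(quals, name) {
  pat <- sprintf("/%s=\"", name)
  i <- regexpr(pat, quals, fixed = TRUE)
  if (i == -1L) return(NULL)
  rest <- substr(quals, i + attr(i, "match.length"), nchar(quals))
  j <- regexpr("\"", rest, fixed = TRUE)
  if (j == -1L) return(rest)
  substr(rest, 1L, j - 1L)
}

#' Write a region record as a minimal GenBank flatfile
#'
#' Intended for fixtures and synthetic genomes: LOCUS, FEATURES (source +
#' CDS with 1-based inclusive locations, `/product` and `/translation`
#' qualifiers) and ORIGIN. Round-trips exactly through [read_genbank()].
#'
#' @param region A [region_record()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(region, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nchar(region$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   PHG",
                     region$id, n), con)
  writeLines(sprintf("DEFINITION  %s.", region$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (f in region$features) {
    loc <- sprintf("%d..%d", f$start + 1L, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    if (nzchar(f$product))
      writeLines(strwrap(sprintf("/product=\"%s\"", f$product),
                         width = 58, indent = 21, exdent = 21), con)
    if (!is.null(f$translation))
      writeLines(strwrap(sprintf("/translation=\"%s\"", f$translation),
                         width = 58, indent = 21, exdent = 21), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(region$sequence)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
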