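#' @importFrom stats pbinom pchisq runif sd setNames
#' @importFrom utils write.table head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# All human-facing output (TSV/GFF3 reports, GenBank writer) is 1-based
# inclusive; conversion happens only at the I/O boundary.

#' Create a CDS feature
#'
#' A protein-coding feature on a region, held in internal 0-based half-open
#' coordinates. `end > start` always; for minus-strand features the interval
#' still runs left-to-right on the forward strand.
#'
#' @param start,end Base offsets, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param product Free-text product description.
#' @param translation Optional amino-acid string (stop trimmed). When absent
#'   it can be derived with [cds_translation()].
#' @param id Optional feature identifier.
#' @return An object of class `cds_feature`.
#' @export
cds_feature <- function(start, end, strand, product = "", translation = NULL,
                        id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("cds_feature: end must be > start")
  if (!strand %in% c("+", "-")) stop("cds_feature: strand must be '+' or '-'")
  if (!is.null(translation)) {
    want <- (end - start) %/% 3L
    # allow the stop codon to have been trimmed from the translation
    if (!nchar(translation) %in% c(want, want - 1L))
      stop("cds_feature: translation length inconsistent with interval")
  }
  structure(list(start = start, end = end, strand = strand,
                 product = product, translation = translation, id = id),
            class = "cds_feature")
}

#' Create a region record
#'
#' A genome or prophage region: sequence over `{A,C,G,T,N}`, CDS features,
#' and the source it was read from.
#'
#' @param id Region identifier (must be non-empty).
#' @param sequence DNA string; upper-cased, `U` converted to `T`, any other
#'   non-ACGTN letter replaced by `N` (with a warning giving the count).
#' @param features List of [cds_feature()] objects, all within the sequence.
#' @param source Provenance text (file path or accession).
#' @return An object of class `region_record`.
#' @export
region_record <- function(id, sequence, features = list(), source = "") {
  if (!nzchar(id)) stop("region_record: id must be non-empty")
  sequence <- clean_dna(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("region_record: sequence must be non-empty")
  for (f in features) {
    stopifnot(inherits(f, "cds_feature"))
    if (f$start < 0L || f$end > n)
      stop(sprintf("region_record '%s': feature [%d,%d) outside [0,%d)",
                   id, f$start, f$end, n))
  }
  structure(list(id = id, sequence = sequence, features = features,
                 source = source),
            class = "region_record")
}

#' @export
print.region_record <- function(x, ...) {
  cat(sprintf("<region_record> %s: %d bp, %d CDS feature(s)\n",
              x$id, nchar(x$sequence), length(x$features)))
  invisible(x)
}

#' Create a reverse-transcriptase hit
#'
#' Marks a CDS as a reverse transcriptase, either from a parsed HMMER domain
#' table (Pfam RT domain) or from the built-in catalytic-motif fallback scan.
#'
#' @param region_id Region the ORF belongs to.
#' @param orf The [cds_feature()] hit.
#' @param score Bit score (`NA` for motif hits).
#' @param source `"domtbl"` or `"motif"`.
#' @return An object of class `rt_hit`.
#' @export
rt_hit <- function(region_id, orf, score = NA_real_,
                   source = c("domtbl", "motif")) {
  source <- match.arg(source)
  stopifnot(inherits(orf, "cds_feature"))
  structure(list(region_id = region_id, orf = orf,
                 score = as.numeric(score), source = source),
            class = "rt_hit")
}

# ---- sequence utilities -----------------------------------------------------

clean_dna <- function(x) {
  x <- chartr("u", "t", toupper(gsub("[ \t\r\n0-9]", "", x)))
  x <- chartr("U", "T", x)
  bad <- gregexpr("[^ACGTN]", x)[[1]]
  if (bad[1] != -1L) {
    warning(sprintf("%d non-ACGTN base(s) replaced by N", length(bad)),
            call. = FALSE)
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    chars[bad] <- "N"
    x <- paste(chars, collapse = "")
  }
  x
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

#' Translate a CDS feature
#'
#' Extracts the feature interval from the region (reverse-complemented for
#' minus-strand features) and translates with the bacterial genetic code
#' (table 11), trimming a trailing stop. Returns the stored `/translation`
#' qualifier when one is present.
#'
#' @param region A [region_record()].
#' @param feat A [cds_feature()] of `region`.
#' @return Amino-acid string.
#' @export
cds_translation <- function(region, feat) {
  if (!is.null(feat$translation)) return(feat$translation)
  nt <- substr(region$sequence, feat$start + 1L, feat$end)
  if (feat$strand == "-") nt <- revcomp(nt)
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

# overlap length of two 0-based half-open intervals
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}
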