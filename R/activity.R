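# Prophage activity from read recruitment: per-base depth over a region,
# mean fold coverage, and the activity verdict (strictly > 10-fold mean
# coverage demonstrates an integrated phage producing virions). SAM is
# parsed as text — the declared input subset is @SQ header lines plus
# mapped records with POS/CIGAR and an NM tag.

parse_sam <- function(sam_path) {
  lines <- readLines(sam_path, warn = FALSE)
  list(header = lines[startsWith(lines, "@")],
       records = lines[!startsWith(lines, "@") & nzchar(lines)])
}

sam_sq_len <- function(header, region_id) {
  sq <- header[startsWith(header, "@SQ")]
  for (l in sq) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", grep("^SN:", f, value = TRUE)[1])
    if (identical(sn, region_id))
      return(as.integer(sub("^LN:", "", grep("^LN:", f, value = TRUE)[1])))
  }
  NA_integer_
}

cigar_ops <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
       op = sub("^[0-9]+", "", m))
}

sam_nm <- function(fields) {
  tag <- grep("^NM:i:", fields[-(1:11)], value = TRUE)
  if (!length(tag)) return(NA_integer_)
  as.integer(sub("^NM:i:", "", tag[1]))
}

#' Per-base coverage of a region from a SAM file
#'
#' Depth is incremented over reference-consuming alignment columns of type
#' `M`, `=` or `X`; deletions (`D`) and skips (`N`) advance the reference
#' without adding depth. Unmapped, secondary and supplementary records are
#' excluded. With an identity threshold, records with
#' `(aligned_cols - NM) / aligned_cols` below it are excluded, where
#' `aligned_cols` counts `M/=/X` columns and NM is the edit-distance tag.
#'
#' @param sam_path SAM text file with an `@SQ` line for `region_id`.
#' @param region_id Reference name to profile.
#' @param region_len Region length in bp; defaults to the `@SQ` `LN` value.
#' @param identity_threshold Minimum alignment identity, or `NULL` for no
#'   filter. A filtered record lacking NM is an error naming the read.
#' @return A `coverage_profile`: `depth` (integer vector), `mean_fold`,
#'   `breadth` (fraction of bases with depth >= 1) and `n_reads_used`.
#' @export
coverage_from_sam <- function(sam_path, region_id, region_len = NULL,
                              identity_threshold = NULL) {
  sam <- parse_sam(sam_path)
  sq_len <- sam_sq_len(sam$header, region_id)
  if (is.na(sq_len)) {
    if (is.null(region_len))
      stop(sprintf("no @SQ line for region '%s' in %s", region_id, sam_path))
  } else if (is.null(region_len)) region_len <- sq_len
  depth <- integer(region_len)
  n_used <- 0L
  for (rec in sam$records) {
    f <- strsplit(rec, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) || bitwAnd(flag, 256L) || bitwAnd(flag, 2048L)) next
    if (f[3] != region_id) next
    ops <- cigar_ops(f[6])
    aligned <- sum(ops$len[ops$op %in% c("M", "=", "X")])
    if (aligned == 0L) next
    if (!is.null(identity_threshold)) {
      nm <- sam_nm(f)
      if (is.na(nm))
        stop(sprintf("record '%s' lacks the NM tag needed for the identity filter",
                     f[1]))
      if ((aligned - nm) / aligned < identity_threshold) next
    }
    pos <- as.integer(f[4]) - 1L                 # 0-based reference cursor
    for (j in seq_along(ops$op)) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        lo <- max(0L, pos); hi <- min(region_len, pos + len)
        if (hi > lo) depth[(lo + 1L):hi] <- depth[(lo + 1L):hi] + 1L
        pos <- pos + len
      } else if (op %in% c("D", "N")) {
        pos <- pos + len
      }
      # I/S/H/P consume no reference
    }
    n_used <- n_used + 1L
  }
  structure(list(region_id = region_id, depth = depth,
                 mean_fold = sum(depth) / region_len,
                 breadth = mean(depth >= 1L),
                 n_reads_used = n_used),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %.2fx mean fold, breadth %.3f (%d reads)\n",
              x$region_id, x$mean_fold, x$breadth, x$n_reads_used))
  invisible(x)
}

#' Classify a region as virion-producing
#'
#' A prophage region is called `active` when its mean fold coverage is
#' strictly greater than the threshold (default 10-fold): read recruitment
#' above that level demonstrates an integrated phage capable of producing
#' virions. Exactly 10.0 is `inactive`.
#'
#' @param profile A `coverage_profile`.
#' @param coverage_threshold Fold-coverage threshold (strict `>`).
#' @return `"active"` or `"inactive"`.
#' @export
classify_active <- function(profile, coverage_threshold = 10) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (profile$mean_fold > coverage_threshold) "active" else "inactive"
}

#' Naive exact-k-mer read placement (test plumbing)
#'
#' A deliberately simple substitute for a production mapper, used to close
#' the simulate-map-cover loop in tests: each read is placed at the unique
#' position where its first k-mer matches the reference exactly, on either
#' strand; reads whose seed is absent or matches more than once are emitted
#' unmapped. CIGAR is always full-length `M`; NM is computed by direct
#' comparison.
#'
#' @param reads Named character vector of read sequences, or a FASTQ path.
#' @param region A [region_record()].
#' @param k Seed length (default 31).
#' @return SAM text (character vector of lines, header first).
#' @export
naive_map <- function(reads, region, k = 31L) {
  if (length(reads) == 1L && file.exists(reads[1]) &&
      is.null(names(reads))) reads <- read_fastq(reads)
  L <- nchar(region$sequence)
  ref <- region$sequence
  ref_rc <- revcomp(ref)
  starts <- seq_len(L - k + 1L)
  kindex <- split(starts, substring(ref, starts, starts + k - 1L))
  out <- c(sprintf("@HD\tVN:1.6\tSO:unsorted"),
           sprintf("@SQ\tSN:%s\tLN:%d", region$id, L))
  nm_count <- function(a, b) {
    sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
  }
  ids <- names(reads) %||% sprintf("read%d", seq_along(reads))
  for (i in seq_along(reads)) {
    r <- toupper(reads[[i]])
    len <- nchar(r)
    unmapped <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", ids[i], r)
    if (len < k) { out <- c(out, unmapped); next }
    seed <- substr(r, 1L, k)
    fwd <- kindex[[seed]] %||% integer(0)              # read as-is at fwd
    rc_seed <- revcomp(seed)
    rc_hits <- kindex[[rc_seed]] %||% integer(0)       # read from minus strand
    # minus-strand placement: read's first k-mer is the RC of the reference
    # window ending the alignment, so alignment start = hit + k - len (1-based)
    rev_pos <- rc_hits + k - len
    rev_pos <- rev_pos[rev_pos >= 1L & rev_pos + len - 1L <= L]
    cand <- rbind(
      if (length(fwd)) cbind(pos = fwd, rev = 0L) else NULL,
      if (length(rev_pos)) cbind(pos = rev_pos, rev = 1L) else NULL)
    if (is.null(cand) || nrow(cand) != 1L) { out <- c(out, unmapped); next }
    pos <- cand[1, "pos"]; is_rev <- cand[1, "rev"] == 1L
    ref_win <- substr(ref, pos, pos + len - 1L)
    seq_out <- if (is_rev) revcomp(r) else r
    nm <- nm_count(seq_out, ref_win)
    out <- c(out, sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                          ids[i], if (is_rev) 16L else 0L, region$id, pos,
                          len, seq_out, nm))
  }
  out
}

read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) stop(sprintf("%s: truncated FASTQ", path))
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  setNames(toupper(lines[seq(2L, length(lines), 4L)]), ids)
}

#' Write reads to FASTQ
#'
#' @param reads Named character vector of sequences.
#' @param path Output file.
#' @param quality Constant per-base quality character.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  ids <- names(reads) %||% sprintf("read%d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads))
    writeLines(c(paste0("@", ids[i]), reads[[i]], "+",
                 strrep(quality, nchar(reads[[i]]))), con)
  invisible(path)
}
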