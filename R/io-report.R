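#' Write a cassette report (TSV or GFF3)
#'
#' The TSV has one row per cassette with RT/TR/VR coordinates (converted to
#' 1-based inclusive), the adenine-mismatch counts, bias fraction and
#' p-value, target-ORF residue span and flags. GFF3 output emits three
#' linked features (RT, TR, VR) per cassette sharing a cassette ID. Output
#' is byte-stable for a fixed cassette order.
#'
#' @param cassettes List of `dgr_cassette` objects (may be empty).
#' @param path Output file.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_cassette_report <- function(cassettes, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") write_cassette_tsv(cassettes, path)
  else write_cassette_gff3(cassettes, path)
  invisible(path)
}

cassette_table <- function(cassettes) {
  cols <- c("region_id", "rank", "rt_start", "rt_end", "rt_strand",
            "tr_start", "tr_end", "vr_start", "vr_end", "cassette_strand",
            "repeat_length",
            "tr_adenine_count", "adenine_mismatches", "total_mismatches",
            "adenine_bias_fraction", "bias_pvalue",
            "target_orf_start", "target_orf_end", "target_orf_product",
            "vr_residue_start", "vr_residue_end", "ambiguous")
  if (!length(cassettes)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(df)
  }
  rows <- lapply(cassettes, function(x) {
    orf <- x$rt$orf
    data.frame(
      region_id = x$region_id, rank = x$rank,
      rt_start = orf$start + 1L, rt_end = orf$end, rt_strand = orf$strand,
      tr_start = x$tr_span[1] + 1L, tr_end = x$tr_span[2],
      vr_start = x$vr_span[1] + 1L, vr_end = x$vr_span[2],
      cassette_strand = x$strand,
      repeat_length = x$repeat_pair$length,
      tr_adenine_count = x$tr_adenine_count,
      adenine_mismatches = x$adenine_mismatch_count,
      total_mismatches = x$total_mismatch_count,
      adenine_bias_fraction = x$adenine_bias_fraction,
      bias_pvalue = signif(x$bias_pvalue, 6),
      target_orf_start = if (is.null(x$target_orf)) NA_integer_ else
        x$target_orf$start + 1L,
      target_orf_end = if (is.null(x$target_orf)) NA_integer_ else
        x$target_orf$end,
      target_orf_product = if (is.null(x$target_orf)) NA_character_ else
        x$target_orf$product,
      vr_residue_start = if (is.null(x$vr_residue_span)) NA_integer_ else
        x$vr_residue_span[1],
      vr_residue_end = if (is.null(x$vr_residue_span)) NA_integer_ else
        x$vr_residue_span[2],
      ambiguous = x$ambiguity_flag,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_cassette_tsv <- function(cassettes, path) {
  df <- cassette_table(cassettes)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

write_cassette_gff3 <- function(cassettes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  i <- 0L
  for (x in cassettes) {
    i <- i + 1L
    cid <- sprintf("dgr%03d", i)
    orf <- x$rt$orf
    line <- function(type, s, e, strand, id, extra = "") {
      sprintf("%s\tdgrscan\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s%s",
              x$region_id, type, s + 1L, e, strand, id, cid, extra)
    }
    writeLines(sprintf(
      "%s\tdgrscan\tmobile_genetic_element\t%d\t%d\t.\t+\t.\tID=%s;Name=DGR_cassette;rank=%d",
      x$region_id, min(orf$start, x$tr_span[1], x$vr_span[1]) + 1L,
      max(orf$end, x$tr_span[2], x$vr_span[2]), cid, x$rank), con)
    writeLines(line("CDS", orf$start, orf$end, orf$strand,
                    paste0(cid, ".rt"), ";product=reverse transcriptase"), con)
    writeLines(line("repeat_region", x$tr_span[1], x$tr_span[2], "+",
                    paste0(cid, ".tr"), ";Name=template_repeat"), con)
    writeLines(line("repeat_region", x$vr_span[1], x$vr_span[2], "+",
                    paste0(cid, ".vr"),
                    sprintf(";Name=variable_repeat;adenine_mismatches=%d",
                            x$adenine_mismatch_count)), con)
  }
}
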