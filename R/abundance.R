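# Fractional abundance of a phage in a read set, and the parameterized
# global-virion calculator.

#' Fractional abundance from read recruitment
#'
#' Counts primary alignments in a SAM file that pass the identity filter
#' (default 97%, computed as `(aligned_cols - NM)/aligned_cols`) and
#' divides by the total read count of the sample. Optionally normalizes
#' per kilobase of reference.
#'
#' @param sam_path SAM text file of reads mapped to the phage genome.
#' @param region_id Reference name of the phage genome.
#' @param total_reads Total quality-filtered reads in the sample.
#' @param identity_threshold Minimum alignment identity (`NULL` disables).
#' @param per_kb Divide the fraction by reference length in kb (requires an
#'   `@SQ` line carrying the length).
#' @param sample_id Label for the output record.
#' @return An `abundance_record`: `recruited_reads`, `total_reads`,
#'   `fractional_abundance`.
#' @export
fractional_abundance <- function(sam_path, region_id, total_reads,
                                 identity_threshold = 0.97, per_kb = FALSE,
                                 sample_id = basename(sam_path)) {
  if (total_reads <= 0) stop("fractional_abundance: total_reads must be > 0")
  sam <- parse_sam(sam_path)
  recruited <- 0L
  for (rec in sam$records) {
    f <- strsplit(rec, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) || bitwAnd(flag, 256L) || bitwAnd(flag, 2048L)) next
    if (f[3] != region_id) next
    if (!is.null(identity_threshold)) {
      ops <- cigar_ops(f[6])
      aligned <- sum(ops$len[ops$op %in% c("M", "=", "X")])
      if (aligned == 0L) next
      nm <- sam_nm(f)
      if (is.na(nm))
        stop(sprintf("record '%s' lacks the NM tag needed for the identity filter",
                     f[1]))
      if ((aligned - nm) / aligned < identity_threshold) next
    }
    recruited <- recruited + 1L
  }
  if (recruited > total_reads)
    stop("fractional_abundance: recruited reads exceed total_reads")
  frac <- recruited / total_reads
  if (per_kb) {
    len <- sam_sq_len(sam$header, region_id)
    if (is.na(len))
      stop(sprintf("per-kb normalization needs an @SQ LN for '%s'", region_id))
    frac <- frac / (len / 1000)
  }
  structure(list(sample_id = sample_id, recruited_reads = recruited,
                 total_reads = total_reads, fractional_abundance = frac,
                 per_kb = per_kb),
            class = "abundance_record")
}

#' Global virion estimate
#'
#' Back-of-the-envelope scale-up: `prevalence x virions_per_carrier x
#' population`. The inputs are deliberately exposed rather than fixed —
#' prevalence is the fraction of people carrying the phage,
#' `virions_per_carrier` is, e.g., gut virions per person times the mean
#' fractional abundance of the phage.
#'
#' @param prevalence Fraction of carriers in `[0, 1]`.
#' @param virions_per_carrier Virions per carrying individual.
#' @param population Number of individuals.
#' @return The estimated global virion count (numeric).
#' @export
global_virions <- function(prevalence, virions_per_carrier, population) {
  if (prevalence < 0 || prevalence > 1)
    stop("global_virions: prevalence must lie in [0, 1]")
  if (virions_per_carrier < 0 || population < 0)
    stop("global_virions: counts must be >= 0")
  prevalence * virions_per_carrier * population
}
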