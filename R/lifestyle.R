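# Phage lifestyle calls from replicate classifier scores, and the
# temperate-enrichment chi-square test.

#' Confident lifestyle call from replicate scores
#'
#' Replicate scores are per-tree probabilities of the temperate lifestyle
#' in `[0, 1]`. A call is confident only when the mean score minus its
#' standard deviation clears the threshold: `mean - sd > threshold` gives
#' `temperate`; symmetrically `(1 - mean) - sd > threshold` gives `lytic`;
#' otherwise no assignment is made (`NA`). The boundary is strict: a margin
#' of exactly 0.5 is not confident.
#'
#' @param scores Numeric vector of replicate scores in `[0, 1]`, length >= 2.
#' @param threshold Confidence margin (default 0.5).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return `"temperate"`, `"lytic"` or `NA_character_`.
#' @export
confident_call <- function(scores, threshold = 0.5,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(scores) < 2L)
    stop("confident_call: need >= 2 replicate scores")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("confident_call: scores must lie in [0, 1]")
  m <- mean(scores)
  s <- sd(scores)
  if (sd_type == "population")
    s <- s * sqrt((length(scores) - 1) / length(scores))
  if (m - s > threshold) return("temperate")
  if ((1 - m) - s > threshold) return("lytic")
  NA_character_
}

#' Read per-phage replicate lifestyle scores from TSV
#'
#' First column is the phage id; remaining columns are replicate scores.
#'
#' @param path TSV file with a header row.
#' @return Named list of numeric score vectors, one per phage.
#' @export
read_lifestyle_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L) stop("lifestyle TSV needs an id column and >= 2 replicates")
  setNames(lapply(seq_len(nrow(df)),
                  function(i) as.numeric(df[i, -1, drop = TRUE])),
           as.character(df[[1]]))
}

#' Chi-square goodness-of-fit enrichment test
#'
#' Tests whether observed class counts (e.g. DGR-bearing phages split into
#' temperate vs lytic) deviate from the proportions of a background
#' composition (e.g. all classified phages in the databases). Expected
#' counts are `sum(observed) * background / sum(background)`; the Pearson
#' statistic is referred to a chi-square upper tail with `classes - 1`
#' degrees of freedom. No continuity correction is applied.
#'
#' @param observed Integer vector of observed counts per class.
#' @param background Positive counts (or proportions) per class defining
#'   the null composition.
#' @return List with `chi2`, `df`, `pvalue` and `expected`.
#' @export
chi_square_enrichment <- function(observed, background) {
  if (length(observed) < 2L || length(observed) != length(background))
    stop("chi_square_enrichment: need >= 2 classes, matching lengths")
  if (any(background <= 0))
    stop("chi_square_enrichment: background counts must all be > 0")
  n <- sum(observed)
  if (n == 0) stop("chi_square_enrichment: no observations")
  expected <- n * background / sum(background)
  if (any(expected < 1))
    warning("expected count < 1 in at least one class; the chi-square ",
            "approximation may be poor", call. = FALSE)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df,
       pvalue = pchisq(chi2, df, lower.tail = FALSE),
       expected = expected)
}
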