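#' Detection parameters
#'
#' Bundles every tunable threshold of the scanner. The defaults for `A_min`
#' and `S_min` are the published DGR screen settings (minimum 10 adenines in
#' the template repeat, minimum 7 adenine substitutions in the variable
#' repeat); the coverage, identity and confidence thresholds are the values
#' used for prophage-activity and lifestyle calls (strictly greater than
#' 10-fold mean coverage, 97% alignment identity, 0.5 confidence margin).
#'
#' @param A_min Minimum adenine count in the TR for a cassette call.
#' @param S_min Minimum adenine-mismatch count (columns where TR has A and
#'   VR differs) for a cassette call.
#' @param rt_window Scan window in bp on each side of the RT ORF.
#' @param seed_k Exact seed k-mer length for repeat discovery; a second pass
#'   at k = 7 runs when no seed of length `seed_k` pairs up.
#' @param min_repeat_len Minimum reported repeat length (bp).
#' @param max_mismatch_fraction Maximum cumulative mismatch fraction during
#'   greedy extension of a repeat pair.
#' @param max_copy_separation Maximum gap (bp) between the two copies.
#' @param coverage_threshold Mean-fold-coverage threshold for the activity
#'   verdict (strict `>`).
#' @param identity_threshold Alignment identity filter for read recruitment.
#' @param confidence_threshold Lifestyle confidence margin.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(A_min = 10L, S_min = 7L, rt_window = 20000L,
                             seed_k = 11L, min_repeat_len = 40L,
                             max_mismatch_fraction = 0.25,
                             max_copy_separation = 5000L,
                             coverage_threshold = 10,
                             identity_threshold = 0.97,
                             confidence_threshold = 0.5) {
  p <- list(A_min = as.integer(A_min), S_min = as.integer(S_min),
            rt_window = as.integer(rt_window), seed_k = as.integer(seed_k),
            min_repeat_len = as.integer(min_repeat_len),
            max_mismatch_fraction = max_mismatch_fraction,
            max_copy_separation = as.integer(max_copy_separation),
            coverage_threshold = coverage_threshold,
            identity_threshold = identity_threshold,
            confidence_threshold = confidence_threshold)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1)) &
          !names(p) %in% character(0)))
    stop("detection_params: all parameters must be positive scalars")
  if (p$max_mismatch_fraction > 1 || p$identity_threshold > 1)
    stop("detection_params: fractions must lie in (0, 1]")
  structure(p, class = "detection_params")
}

#' Merge parameter overrides onto defaults
#'
#' Later sources win: defaults, then a YAML config file, then explicit
#' overrides (CLI flags). Unknown keys are rejected.
#'
#' @param config_path Optional YAML file of `key: value` pairs.
#' @param overrides Named list of explicit overrides.
#' @return A [detection_params()] object.
#' @export
resolve_params <- function(config_path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(config_path)) {
    if (!file.exists(config_path))
      stop(sprintf("config file not found: %s", config_path))
    vals <- yaml::read_yaml(config_path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(detection_params))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown parameter(s): %s", paste(bad, collapse = ", ")))
  do.call(detection_params, vals)
}
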