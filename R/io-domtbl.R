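#' Read reverse-transcriptase hits from a HMMER domain table
#'
#' Parses HMMER3 per-domain tabular output (`--domtblout`) and keeps rows
#' whose query or target accession is the Pfam reverse-transcriptase domain
#' PF00078 (any version suffix, e.g. `PF00078.17`) or whose HMM name is
#' `RVT_1`. Comment lines (`#`) are ignored. Target names of the form
#' `<region_id>:<orf_index>` (1-based index into the region's feature list)
#' are resolved against `regions` when supplied.
#'
#' @param path domtblout text file.
#' @param regions Optional list of [region_record()] used to attach each hit
#'   to its ORF; hits naming unknown regions/ORFs are dropped with a warning.
#' @param accession Pfam accession to keep (default `"PF00078"`).
#' @return List of [rt_hit()] (empty when nothing matches).
#' @export
read_domtbl <- function(path, regions = NULL, accession = "PF00078") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  hits <- list()
  acc_re <- sprintf("^%s(\\.[0-9]+)?$", accession)
  region_index <- if (!is.null(regions))
    setNames(regions, vapply(regions, `[[`, "", "id")) else NULL
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop(sprintf("%s: line %d has %d columns (domtblout needs >= 22)",
                   path, i, length(f)))
    # columns: 1 target name, 2 target acc, 4 query name, 5 query acc,
    # 8 full-sequence bit score
    is_rt <- grepl(acc_re, f[2]) || grepl(acc_re, f[5]) ||
      f[1] == "RVT_1" || f[4] == "RVT_1"
    if (!is_rt) next
    target <- f[1]
    parts <- strsplit(target, ":", fixed = TRUE)[[1]]
    region_id <- parts[1]
    orf_idx <- if (length(parts) > 1L) suppressWarnings(as.integer(parts[2]))
      else NA_integer_
    orf <- NULL
    if (!is.null(region_index)) {
      reg <- region_index[[region_id]]
      if (is.null(reg) || is.na(orf_idx) || orf_idx < 1L ||
          orf_idx > length(reg$features)) {
        warning(sprintf("%s: hit '%s' does not name a known region ORF; dropped",
                        path, target), call. = FALSE)
        next
      }
      orf <- reg$features[[orf_idx]]
    }
    score <- suppressWarnings(as.numeric(f[8]))
    hits[[length(hits) + 1L]] <- if (is.null(orf)) {
      structure(list(region_id = region_id, orf = NULL, orf_index = orf_idx,
                     score = score, source = "domtbl"), class = "rt_hit")
    } else {
      h <- rt_hit(region_id, orf, score = score, source = "domtbl")
      h$orf_index <- orf_idx
      h
    }
  }
  hits
}
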