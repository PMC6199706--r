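#' Read a FASTA file into region records
#'
#' Sequences are upper-cased, `U` is converted to `T`, and any other letter
#' outside `{A,C,G,T,N}` becomes `N` (a single warning reports the count).
#'
#' @param path FASTA file.
#' @return List of [region_record()], in file order. The id is the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  lapply(seq_along(set), function(i)
    region_record(ids[i], as.character(set[[i]]), source = path))
}

#' Write region records to FASTA
#'
#' @param regions List of [region_record()] (or a single one).
#' @param path Output file.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(regions, path, width = 70L) {
  if (inherits(regions, "region_record")) regions <- list(regions)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in regions) {
    writeLines(paste0(">", r$id), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
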