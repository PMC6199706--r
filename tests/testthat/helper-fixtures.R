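# Fixture builders: every fixture is generated in code at test time.

`%+%` <- function(a, b) paste0(a, b)

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# toy GenBank flatfile text, built by hand (independent of write_genbank)
toy_genbank_lines <- function() {
  c("LOCUS       toyphage 60 bp    DNA     linear   PHG",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..9",
    '                     /product="tiny orf"',
    "     CDS             complement(20..40)",
    '                     /product="minus orf"',
    "ORIGIN",
    "        1 atggcctaac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtaa gggtttccca",
    "//")
}

# minimal domtblout: 22 fixed columns + description
domtbl_line <- function(target, tacc, query, qacc, score = 55.2) {
  paste(target, tacc, "300", query, qacc, "250",
        "1e-20", score, "10.1", "1", "1", "1e-20", "1e-20", score, "10.1",
        "5", "200", "10", "190", "8", "195", "0.95", "test hit")
}

# SAM text with one @SQ line and given record lines
sam_text <- function(region_id, region_len, records) {
  c(sprintf("@HD\tVN:1.6\tSO:unsorted"),
    sprintf("@SQ\tSN:%s\tLN:%d", region_id, region_len),
    records)
}

sam_record <- function(qname, flag, rname, pos, cigar, seq, nm = NULL) {
  base <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  qname, flag, rname, pos, cigar, seq)
  if (!is.null(nm)) base <- paste0(base, sprintf("\tNM:i:%d", nm))
  base
}

# plant an exact (or mutated) duplication in otherwise-random sequence and
# return the pieces; used by detector tests that need full control. The
# flanks of the two copies are made columnwise divergent ("clean flanks"),
# so the planted boundaries are the unique maximal-scoring ones and exact
# recovery can be asserted.
plant_duplication <- function(total_len, rep_len, gap, n_mut = 0L,
                              seed = 1L, flank_div = 45L) {
  set.seed(seed)
  rep1 <- rand_seq(rep_len)
  rep2 <- rep1
  if (n_mut > 0L) {
    chars <- strsplit(rep2, "", fixed = TRUE)[[1]]
    idx <- sample(seq(2L, rep_len - 1L), n_mut)
    chars[idx] <- vapply(chars[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    rep2 <- paste(chars, collapse = "")
  }
  diverge <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(vapply(chars, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), ""), collapse = "")
  }
  pad1 <- (total_len - 2L * rep_len - gap) %/% 2L
  pad2 <- total_len - 2L * rep_len - gap - pad1
  stopifnot(pad1 >= flank_div, pad2 >= flank_div, gap >= 2L * flank_div)
  left2 <- rand_seq(flank_div)                 # flank left of copy2
  right2 <- rand_seq(flank_div)                # flank right of copy2
  gap_mid <- rand_seq(gap - 2L * flank_div)
  list(seq = paste0(rand_seq(pad1 - flank_div), diverge(left2), rep1,
                    diverge(right2), gap_mid, left2, rep2, right2,
                    rand_seq(pad2 - flank_div)),
       start1 = pad1, start2 = pad1 + rep_len + gap, rep1 = rep1,
       rep2 = rep2)
}
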