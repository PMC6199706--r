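# TR/VR repeat-pair discovery and DGR calling.
#
# The scanner looks for direct (same-strand, gapless) repeat pairs near a
# reverse-transcriptase ORF by shared exact k-mer seeds, extends each seed
# greedily in both directions while the cumulative mismatch fraction stays
# within bounds, trims so both termini are matching columns, and then
# orients the two copies into template (TR) and variable (VR) repeat by
# adenine ownership of the mismatched columns. A pair is called a DGR
# cassette when the TR carries at least `A_min` adenines and at least
# `S_min` mismatch columns are adenine in the TR — the published screen
# defaults (10 and 7).

#' Find direct repeat pairs near a reverse-transcriptase locus
#'
#' Seeds are exact shared k-mers (`params$seed_k`; a second pass at k = 7
#' runs if the first finds nothing, so that short clean stretches between
#' dense mismatches still seed). Each seed pair is extended greedily while
#' the cumulative mismatch fraction stays at or below
#' `params$max_mismatch_fraction`, then trimmed so both terminal columns
#' match. Duplicate seeds of one repeat collapse to one maximal pair.
#'
#' @param region A [region_record()].
#' @param anchor An [rt_hit()] whose ORF lies inside `region`; the scan is
#'   restricted to `params$rt_window` bp on each side of that ORF.
#' @param params [detection_params()].
#' @return List of repeat pairs (class `repeat_pair`), sorted by
#'   `copy1_start`, then decreasing length. Each has 0-based half-open
#'   copy coordinates, `length`, 0-based `mismatch_columns` (columns where
#'   the copies differ and neither base is N) and `orientation = "same"`.
#' @export
find_repeat_pairs <- function(region, anchor, params = detection_params()) {
  orf <- anchor$orf
  L <- nchar(region$sequence)
  if (is.null(orf) || orf$start < 0L || orf$end > L)
    stop("find_repeat_pairs: anchor ORF outside region")
  if (L < params$seed_k) return(list())
  w0 <- max(0L, orf$start - params$rt_window)
  w1 <- min(L, orf$end + params$rt_window)
  win <- strsplit(substr(region$sequence, w0 + 1L, w1), "", fixed = TRUE)[[1]]

  pairs <- seed_extend_pairs(win, params$seed_k, params)
  if (!length(pairs)) pairs <- seed_extend_pairs(win, 7L, params)
  if (!length(pairs)) return(list())

  # drop pairs nested in a longer overlapping pair (duplicate seed products
  # at shifted offsets); then sort
  keep <- logical(length(pairs))
  ord <- order(-vapply(pairs, `[[`, 0L, "length"))
  accepted <- list()
  for (i in ord) {
    p <- pairs[[i]]
    dup <- any(vapply(accepted, function(q) {
      o1 <- interval_overlap(p$copy1_start, p$copy1_end,
                             q$copy1_start, q$copy1_end)
      o2 <- interval_overlap(p$copy2_start, p$copy2_end,
                             q$copy2_start, q$copy2_end)
      o1 > 0.5 * p$length && o2 > 0.5 * p$length
    }, logical(1)))
    if (!dup) {
      accepted[[length(accepted) + 1L]] <- p
      keep[i] <- TRUE
    }
  }
  pairs <- pairs[keep]

  pairs <- lapply(pairs, function(p) {
    p$copy1_start <- p$copy1_start + w0; p$copy1_end <- p$copy1_end + w0
    p$copy2_start <- p$copy2_start + w0; p$copy2_end <- p$copy2_end + w0
    p$region_id <- region$id
    p
  })
  ord <- order(vapply(pairs, `[[`, 0L, "copy1_start"),
               -vapply(pairs, `[[`, 0L, "length"))
  pairs[ord]
}

# seed, extend and trim within a character-vector window; 0-based coords
seed_extend_pairs <- function(win, k, params) {
  n <- length(win)
  if (n < 2L * k) return(list())
  s <- paste(win, collapse = "")
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  idx <- split(starts[ok] - 1L, kmers[ok])       # 0-based seed starts
  idx <- idx[lengths(idx) >= 2L]
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (pos in idx) {
    if (length(pos) > 50L) next                  # low-complexity guard
    for (a in seq_len(length(pos) - 1L)) for (b in (a + 1L):length(pos)) {
      p1 <- pos[a]; p2 <- pos[b]
      d <- p2 - p1
      if (d < k) next                            # overlapping copies
      pr <- extend_seed(win, p1, p2, k, params$max_mismatch_fraction)
      if (is.null(pr)) next
      if (pr$length < params$min_repeat_len) next
      if (pr$copy2_start < pr$copy1_end) next    # overlap after extension
      if (pr$copy2_start - pr$copy1_end > params$max_copy_separation) next
      key <- sprintf("%d:%d:%d", pr$copy1_start, pr$copy2_start, pr$length)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- pr
    }
  }
  out
}

extend_seed <- function(win, p1, p2, k, max_mm_frac) {
  n <- length(win)
  d <- p2 - p1
  # columns are offsets i relative to p1/p2; seed occupies 0..k-1
  lo <- 0L; hi <- k - 1L; mm <- 0L
  # right extension
  i <- hi + 1L
  while (p2 + i < n && i < d) {                  # i < d keeps copies disjoint
    c1 <- win[p1 + i + 1L]; c2 <- win[p2 + i + 1L]
    is_mm <- (c1 != c2) || c1 == "N" || c2 == "N"
    if (is_mm && (mm + 1L) / (i - lo + 1L) > max_mm_frac) break
    if (is_mm) mm <- mm + 1L
    hi <- i; i <- i + 1L
  }
  # trim the right end back to a matching column and recount, so that
  # mismatches accumulated while coasting into divergent flanking sequence
  # do not choke the left extension
  while (hi >= lo) {
    c1 <- win[p1 + hi + 1L]; c2 <- win[p2 + hi + 1L]
    if (c1 == c2 && c1 != "N") break
    hi <- hi - 1L
  }
  if (hi < lo) return(NULL)
  cc1 <- win[(p1 + lo):(p1 + hi) + 1L]
  cc2 <- win[(p2 + lo):(p2 + hi) + 1L]
  mm <- sum(cc1 != cc2 | cc1 == "N" | cc2 == "N")
  # left extension
  i <- lo - 1L
  while (p1 + i >= 0L && (hi - i + 1L) <= d) {
    c1 <- win[p1 + i + 1L]; c2 <- win[p2 + i + 1L]
    is_mm <- (c1 != c2) || c1 == "N" || c2 == "N"
    if (is_mm && (mm + 1L) / (hi - i + 1L) > max_mm_frac) break
    if (is_mm) mm <- mm + 1L
    lo <- i; i <- i - 1L
  }
  # trim so both termini are matching non-N columns; interior mismatches
  # (including ones near the edges) are kept
  while (lo <= hi) {
    c1 <- win[p1 + lo + 1L]; c2 <- win[p2 + lo + 1L]
    if (c1 == c2 && c1 != "N") break
    lo <- lo + 1L
  }
  while (hi >= lo) {
    c1 <- win[p1 + hi + 1L]; c2 <- win[p2 + hi + 1L]
    if (c1 == c2 && c1 != "N") break
    hi <- hi - 1L
  }
  len <- hi - lo + 1L
  if (len <= 0L) return(NULL)
  s1 <- p1 + lo; s2 <- p2 + lo
  cols1 <- win[(s1 + 1L):(s1 + len)]
  cols2 <- win[(s2 + 1L):(s2 + len)]
  mm_cols <- which(cols1 != cols2 & cols1 != "N" & cols2 != "N") - 1L
  structure(list(region_id = NA_character_,
                 copy1_start = s1, copy1_end = s1 + len,
                 copy2_start = s2, copy2_end = s2 + len,
                 length = len, mismatch_columns = mm_cols,
                 orientation = "same"),
            class = "repeat_pair")
}

repeat_copy_seq <- function(region, start, len) {
  substr(region$sequence, start + 1L, start + len)
}

#' Orient a repeat pair into template and variable repeat
#'
#' Mutagenic retrohoming substitutes only at template-repeat adenines, so
#' the donor copy (TR) owns the adenines at mismatched columns. For each
#' copy the adenines at mismatch columns are counted; the copy with more is
#' the TR. On a tie, CDS evidence breaks it (the copy lying inside an
#' annotated ORF is the VR — the diversified copy sits in its target gene);
#' if that is also uninformative, copy1 is declared TR and the ambiguity
#' flag is set.
#'
#' @param pair A `repeat_pair` with at least one mismatch column.
#' @param region The [region_record()] the pair was found in.
#' @return List with `tr_span`, `vr_span` (0-based half-open `c(start,end)`),
#'   `strand` (`"+"` when the cassette reads on the forward strand, `"-"`
#'   when adenine ownership appears as thymine ownership, i.e. the cassette
#'   lies on the reverse strand) and `ambiguity_flag`.
#' @export
orient_tr_vr <- function(pair, region) {
  if (!length(pair$mismatch_columns))
    stop("identical repeats: orientation undefined")
  s1 <- repeat_copy_seq(region, pair$copy1_start, pair$length)
  s2 <- repeat_copy_seq(region, pair$copy2_start, pair$length)
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  mm <- pair$mismatch_columns + 1L
  # adenine ownership on the forward strand; a minus-strand cassette shows
  # the same signal as thymine ownership
  a1 <- sum(c1[mm] == "A"); t1 <- sum(c1[mm] == "T")
  a2 <- sum(c2[mm] == "A"); t2 <- sum(c2[mm] == "T")
  span1 <- c(pair$copy1_start, pair$copy1_end)
  span2 <- c(pair$copy2_start, pair$copy2_end)
  score1 <- max(a1, t1); score2 <- max(a2, t2)
  if (score1 > score2)
    return(list(tr_span = span1, vr_span = span2,
                strand = if (a1 >= t1) "+" else "-", ambiguity_flag = FALSE))
  if (score2 > score1)
    return(list(tr_span = span2, vr_span = span1,
                strand = if (a2 >= t2) "+" else "-", ambiguity_flag = FALSE))
  # tie: the copy inside an annotated CDS is the VR (the diversified copy
  # sits in its target gene)
  in_cds <- function(s, e) any(vapply(region$features, function(f)
    interval_overlap(s, e, f$start, f$end) > 0L, logical(1)))
  cds1 <- in_cds(span1[1], span1[2])
  cds2 <- in_cds(span2[1], span2[2])
  strand_for <- function(a, t) if (a >= t) "+" else "-"
  if (xor(cds1, cds2)) {
    if (cds2) list(tr_span = span1, vr_span = span2,
                   strand = strand_for(a1, t1), ambiguity_flag = FALSE)
    else list(tr_span = span2, vr_span = span1,
              strand = strand_for(a2, t2), ambiguity_flag = FALSE)
  } else {
    list(tr_span = span1, vr_span = span2, strand = strand_for(a1, t1),
         ambiguity_flag = TRUE)
  }
}

#' Adenine-specific mismatch statistics for a TR/VR pair
#'
#' Counts differing columns between equal-length, gapless TR and VR
#' sequences (columns containing N are never counted), the subset where the
#' TR base is adenine, their fraction, and a one-sided binomial tail
#' p-value for adenine enrichment: `P(X >= adenine | n = total, p = f_A)`
#' where `f_A` is the adenine fraction of the TR itself
#' (composition-aware null; descriptive, no multiplicity correction).
#'
#' @param tr_seq,vr_seq Equal-length DNA strings.
#' @return List with `total_mismatches`, `adenine_mismatches`,
#'   `bias_fraction`, `bias_pvalue` (the latter two `NA` when there are no
#'   mismatches).
#' @export
adenine_bias <- function(tr_seq, vr_seq) {
  if (nchar(tr_seq) != nchar(vr_seq))
    stop("adenine_bias: sequences must have equal length")
  t <- strsplit(toupper(tr_seq), "", fixed = TRUE)[[1]]
  v <- strsplit(toupper(vr_seq), "", fixed = TRUE)[[1]]
  diff <- t != v & t != "N" & v != "N"
  total <- sum(diff)
  adenine <- sum(diff & t == "A")
  if (total == 0L)
    return(list(total_mismatches = 0L, adenine_mismatches = 0L,
                bias_fraction = NA_real_, bias_pvalue = NA_real_))
  f_a <- sum(t == "A") / sum(t != "N")
  p <- pbinom(adenine - 1L, total, f_a, lower.tail = FALSE)
  list(total_mismatches = total, adenine_mismatches = adenine,
       bias_fraction = adenine / total, bias_pvalue = p)
}

#' Call DGR cassettes in a region
#'
#' For each reverse-transcriptase hit, discovers repeat pairs in its
#' neighbourhood ([find_repeat_pairs()]), orients each into TR/VR
#' ([orient_tr_vr()]), and retains pairs whose TR carries at least
#' `params$A_min` adenines and at least `params$S_min` adenine mismatches.
#' Retained cassettes are ranked by proximity to the RT ORF (rank 1 =
#' closest); the VR's target ORF (the CDS with the largest overlap) and the
#' 1-based residue interval of the overlap in that ORF's translation are
#' attached when present.
#'
#' @param region A [region_record()].
#' @param rt_hits List of [rt_hit()] (empty list returns no cassettes).
#' @param params [detection_params()].
#' @return List of `dgr_cassette` objects.
#' @export
call_dgr <- function(region, rt_hits, params = detection_params()) {
  kept <- list(); dists <- numeric(0); keys <- character(0)
  for (hit in rt_hits) {
    pairs <- find_repeat_pairs(region, hit, params)
    for (p in pairs) {
      if (!length(p$mismatch_columns)) next
      ori <- orient_tr_vr(p, region)
      tr_seq <- substr(region$sequence, ori$tr_span[1] + 1L, ori$tr_span[2])
      vr_seq <- substr(region$sequence, ori$vr_span[1] + 1L, ori$vr_span[2])
      if (ori$strand == "-") {                   # score on the cassette strand
        tr_seq <- revcomp(tr_seq); vr_seq <- revcomp(vr_seq)
      }
      bias <- adenine_bias(tr_seq, vr_seq)
      tr_a <- sum(strsplit(tr_seq, "", fixed = TRUE)[[1]] == "A")
      if (tr_a < params$A_min || bias$adenine_mismatches < params$S_min) next
      cass <- build_cassette(region, p, ori, bias, tr_a, hit)
      s <- min(p$copy1_start, p$copy2_start)
      e <- max(p$copy1_end, p$copy2_end)
      d <- if (interval_overlap(s, e, hit$orf$start, hit$orf$end) > 0L) 0
           else min(abs(s - hit$orf$end), abs(hit$orf$start - e))
      key <- sprintf("%d:%d:%d:%d", ori$tr_span[1], ori$tr_span[2],
                     ori$vr_span[1], ori$vr_span[2])
      prev <- match(key, keys)
      if (!is.na(prev)) {
        # same pair reachable from several RT windows: keep the closest RT
        if (d < dists[prev]) { kept[[prev]] <- cass; dists[prev] <- d }
      } else {
        kept[[length(kept) + 1L]] <- cass
        dists <- c(dists, d); keys <- c(keys, key)
      }
    }
  }
  if (!length(kept)) return(list())
  ord <- order(dists)
  kept <- kept[ord]
  for (r in seq_along(kept)) kept[[r]]$rank <- r
  kept
}

build_cassette <- function(region, pair, ori, bias, tr_a, hit) {
  target <- NULL; residue_span <- NULL
  ov <- vapply(region$features, function(f)
    interval_overlap(ori$vr_span[1], ori$vr_span[2], f$start, f$end),
    integer(1))
  if (length(ov) && max(ov) > 0L) {
    f <- region$features[[which.max(ov)]]
    target <- f
    os <- max(ori$vr_span[1], f$start)
    oe <- min(ori$vr_span[2], f$end)
    if (f$strand == "+") {
      residue_span <- c((os - f$start) %/% 3L + 1L,
                        (oe - 1L - f$start) %/% 3L + 1L)
    } else {
      residue_span <- c((f$end - oe) %/% 3L + 1L,
                        (f$end - os - 1L) %/% 3L + 1L)
    }
  }
  structure(list(region_id = region$id, repeat_pair = pair,
                 tr_span = ori$tr_span, vr_span = ori$vr_span,
                 strand = ori$strand, rt = hit,
                 tr_adenine_count = tr_a,
                 adenine_mismatch_count = bias$adenine_mismatches,
                 total_mismatch_count = bias$total_mismatches,
                 adenine_bias_fraction = bias$bias_fraction,
                 bias_pvalue = bias$bias_pvalue,
                 target_orf = target,
                 vr_residue_span = residue_span,
                 ambiguity_flag = ori$ambiguity_flag,
                 rank = NA_integer_),
            class = "dgr_cassette")
}

#' @export
print.dgr_cassette <- function(x, ...) {
  cat(sprintf(paste0("<dgr_cassette> %s rank %s: %d bp repeat, ",
                     "TR %d-%d / VR %d-%d (1-based), %d/%d adenine mismatches",
                     " (bias %.2f)\n"),
              x$region_id, x$rank, x$repeat_pair$length,
              x$tr_span[1] + 1L, x$tr_span[2], x$vr_span[1] + 1L, x$vr_span[2],
              x$adenine_mismatch_count, x$total_mismatch_count,
              x$adenine_bias_fraction))
  invisible(x)
}

#' Motif-based reverse-transcriptase fallback scan
#'
#' Flags ORFs whose translation is at least 200 aa and contains the RT
#' catalytic core motif `[YFLIVM].DD` (the YXDD box). A crude stand-in for
#' a profile-HMM search, used when no precomputed domain table is supplied.
#'
#' @param region A [region_record()] with CDS features.
#' @return List of [rt_hit()] with `source = "motif"`.
#' @export
motif_rt_scan <- function(region) {
  hits <- list()
  for (f in region$features) {
    aa <- cds_translation(region, f)
    if (nchar(aa) >= 200L && grepl("[YFLIVM].DD", aa)) {
      h <- rt_hit(region$id, f, source = "motif")
      hits[[length(hits) + 1L]] <- h
    }
  }
  hits
}
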