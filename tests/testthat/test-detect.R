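fake_anchor <- function(region, at = NULL) {
  # an RT anchor in the middle of the region, for tests that only need a
  # scan window
  L <- nchar(region$sequence)
  s <- if (is.null(at)) max(0L, L %/% 2L - 50L) else at
  rt_hit(region$id, cds_feature(s, min(L, s + 99L), "+"), source = "motif")
}

test_that("find_repeat_pairs recovers a planted exact duplication", {
  p <- plant_duplication(1000L, 117L, gap = 300L, seed = 5)
  reg <- region_record("r", p$seq)
  pairs <- find_repeat_pairs(reg, fake_anchor(reg))
  expect_length(pairs, 1)
  expect_equal(pairs[[1]]$length, 117L)
  expect_equal(pairs[[1]]$copy1_start, p$start1)
  expect_equal(pairs[[1]]$copy2_start, p$start2)
  expect_length(pairs[[1]]$mismatch_columns, 0)
})

test_that("find_repeat_pairs recovers a mismatched duplication with its columns", {
  p <- plant_duplication(1500L, 117L, gap = 300L, n_mut = 14L, seed = 9)
  reg <- region_record("r", p$seq)
  pairs <- find_repeat_pairs(reg, fake_anchor(reg))
  expect_length(pairs, 1)
  expect_equal(pairs[[1]]$copy1_start, p$start1)
  expect_equal(pairs[[1]]$copy2_start, p$start2)
  expect_equal(pairs[[1]]$length, 117L)
  truth_cols <- which(strsplit(p$rep1, "")[[1]] != strsplit(p$rep2, "")[[1]]) - 1L
  expect_equal(pairs[[1]]$mismatch_columns, truth_cols)
})

test_that("no-repeat regions yield empty results, agreeing with brute force", {
  set.seed(31)
  found_any <- FALSE
  for (i in 1:10) {
    s <- rand_seq(2000L)
    reg <- region_record("r", s)
    pairs <- find_repeat_pairs(reg, fake_anchor(reg))
    # brute force: any exact repeat >= min_repeat_len anywhere?
    oracle <- brute_force_has_repeat(s, 40L)
    exact_pairs <- Filter(function(p) length(p$mismatch_columns) == 0, pairs)
    if (oracle) found_any <- TRUE
    expect_equal(length(exact_pairs) > 0, oracle)
  }
  expect_false(found_any)  # 40 bp exact repeats in 2 kb random DNA: none
})

test_that("find_repeat_pairs matches the brute-force oracle on exact repeats", {
  for (seed in 1:5) {
    p <- plant_duplication(2000L, sample(40:120, 1), gap = sample(100:600, 1),
                           seed = seed + 100)
    reg <- region_record("r", p$seq)
    pairs <- find_repeat_pairs(reg, fake_anchor(reg))
    oracle <- brute_force_exact_repeats(p$seq, 40L)
    expect_gte(length(pairs), 1)
    best <- pairs[[which.max(vapply(pairs, `[[`, 0L, "length"))]]
    omax <- oracle[[which.max(vapply(oracle, `[`, 0L, "len"))]]
    expect_equal(best$copy1_start, unname(omax["start1"]))
    expect_equal(best$copy2_start, unname(omax["start2"]))
    expect_equal(best$length, unname(omax["len"]))
  }
})

test_that("anchors outside the region are rejected; short regions are empty", {
  reg <- region_record("r", rand_seq(100L))
  bad <- rt_hit("r", cds_feature(90L, 200L, "+"))
  expect_error(find_repeat_pairs(region_record("r", rand_seq(100L)), bad),
               "outside")
  tiny <- region_record("t", "ACGTACGT")
  expect_length(find_repeat_pairs(tiny, rt_hit("t", cds_feature(0L, 6L, "+"))),
                0)
})

make_pair <- function(region, s1, s2, len) {
  c1 <- strsplit(substr(region$sequence, s1 + 1, s1 + len), "")[[1]]
  c2 <- strsplit(substr(region$sequence, s2 + 1, s2 + len), "")[[1]]
  structure(list(region_id = region$id,
                 copy1_start = s1, copy1_end = s1 + len,
                 copy2_start = s2, copy2_end = s2 + len, length = len,
                 mismatch_columns = which(c1 != c2) - 1L,
                 orientation = "same"),
            class = "repeat_pair")
}

test_that("orient_tr_vr assigns the adenine-owning copy as TR", {
  # copy1 all-A at mismatch columns, copy2 C/G: unambiguous
  c1 <- strrep("A", 14); c2 <- strrep("C", 7) %+% strrep("G", 7)
  reg <- region_record("r", paste0(rand_seq(10), c1, rand_seq(20), c2,
                                   rand_seq(10)))
  pair <- make_pair(reg, 10L, 44L, 14L)
  ori <- orient_tr_vr(pair, reg)
  expect_equal(ori$tr_span, c(10L, 24L))
  expect_equal(ori$vr_span, c(44L, 58L))
  expect_false(ori$ambiguity_flag)
  expect_equal(ori$strand, "+")
})

test_that("orientation ties break by CDS overlap, else flag ambiguity", {
  # both copies have A at 3 of 6 mismatch columns
  c1 <- "AAAGGG"; c2 <- "CCCAAA"
  base <- paste0(rand_seq(30), c1, rand_seq(30), c2, rand_seq(30))
  # only copy2 (offset 66..72) lies inside a CDS -> copy2 is VR
  reg <- region_record("r", base,
                       features = list(cds_feature(60L, 90L, "+")))
  pair <- make_pair(reg, 30L, 66L, 6L)
  ori <- orient_tr_vr(pair, reg)
  expect_equal(ori$tr_span, c(30L, 36L))
  expect_false(ori$ambiguity_flag)

  # no CDS at all: declared convention copy1 = TR, flagged
  reg2 <- region_record("r", base)
  ori2 <- orient_tr_vr(pair, reg2)
  expect_equal(ori2$tr_span, c(30L, 36L))
  expect_true(ori2$ambiguity_flag)
})

test_that("orientation is symmetric under copy relabeling", {
  sim <- plant_cassette(sim_params(seed = 21, genome_len = 3000))
  pairs <- find_repeat_pairs(sim$region, sim$rt_hit)
  p <- pairs[[1]]
  swapped <- p
  swapped$copy1_start <- p$copy2_start; swapped$copy1_end <- p$copy2_end
  swapped$copy2_start <- p$copy1_start; swapped$copy2_end <- p$copy1_end
  o1 <- orient_tr_vr(p, sim$region)
  o2 <- orient_tr_vr(swapped, sim$region)
  expect_equal(o1$tr_span, o2$tr_span)
  expect_equal(o1$vr_span, o2$vr_span)
})

test_that("identical repeats cannot be oriented", {
  p <- plant_duplication(600L, 60L, gap = 100L, seed = 3)
  reg <- region_record("r", p$seq)
  pair <- make_pair(reg, p$start1, p$start2, 60L)
  expect_error(orient_tr_vr(pair, reg), "orientation undefined")
})

test_that("adenine_bias counts, fraction and p-value behave as specified", {
  # all 14 mismatches at TR adenines -> fraction 1.0
  tr <- strrep("A", 14) %+% strrep("C", 86)
  vr <- strrep("G", 14) %+% strrep("C", 86)
  b <- adenine_bias(tr, vr)
  expect_equal(b$total_mismatches, 14L)
  expect_equal(b$adenine_mismatches, 14L)
  expect_equal(b$bias_fraction, 1.0)

  # identical sequences -> zero counts, undefined fraction/p
  b0 <- adenine_bias("ACGTACGT", "ACGTACGT")
  expect_equal(b0$total_mismatches, 0L)
  expect_true(is.na(b0$bias_fraction))
  expect_true(is.na(b0$bias_pvalue))

  # 8 bp half-adenine TR, one A and one C mismatched: n=2, p=0.5
  b2 <- adenine_bias("AAAACCCC", "AAACCCCG")
  expect_equal(b2$total_mismatches, 2L)
  expect_equal(b2$adenine_mismatches, 1L)
  expect_equal(b2$bias_fraction, 0.5)
  expect_equal(b2$bias_pvalue, exact_binom_tail(1, 2, 0.5), tolerance = 1e-12)

  expect_error(adenine_bias("ACGT", "ACG"), "equal length")
})

test_that("adenine_bias ignores N-containing columns", {
  b <- adenine_bias("AANA", "CANC")
  expect_equal(b$total_mismatches, 2L)   # N column excluded
  expect_equal(b$adenine_mismatches, 2L)
})

test_that("call_dgr applies the adenine thresholds at their boundaries", {
  # 6 forced adenine mismatches: below S_min = 7, never called
  sim6 <- plant_cassette(sim_params(seed = 2, genome_len = 3000,
                                    n_mismatches = 6L))
  expect_length(call_dgr(sim6$region, list(sim6$rt_hit)), 0)
  # exactly 7: called
  sim7 <- plant_cassette(sim_params(seed = 2, genome_len = 3000,
                                    n_mismatches = 7L))
  cass <- call_dgr(sim7$region, list(sim7$rt_hit))
  expect_length(cass, 1)
  expect_equal(cass[[1]]$adenine_mismatch_count, 7L)
  # TR with too few adenines: not called even with enough mismatches
  simA <- plant_cassette(sim_params(seed = 2, genome_len = 3000,
                                    tr_adenine_count = 9L, n_mismatches = 8L))
  expect_length(call_dgr(simA$region, list(simA$rt_hit)), 0)
})

test_that("call_dgr attaches the target ORF and residue span", {
  sim <- plant_cassette(sim_params(seed = 13, genome_len = 4000))
  cass <- call_dgr(sim$region, list(sim$rt_hit))
  expect_length(cass, 1)
  cc <- cass[[1]]
  expect_equal(cc$target_orf$product, "DGR target protein")
  expect_equal(cc$vr_residue_span, sim$truth$target_residue_span)
  expect_equal(cc$rank, 1L)
  expect_equal(cc$adenine_bias_fraction, 1.0)
  # bias p-value is the exact binomial tail under the TR's own composition
  f_a <- cc$tr_adenine_count / 117
  expect_equal(cc$bias_pvalue,
               exact_binom_tail(cc$adenine_mismatch_count,
                                cc$total_mismatch_count, f_a),
               tolerance = 1e-10)
})

test_that("scanning the reverse complement yields the reflected cassette", {
  sim <- plant_cassette(sim_params(seed = 17, genome_len = 3000))
  cass <- call_dgr(sim$region, list(sim$rt_hit))[[1]]
  L <- nchar(sim$region$sequence)
  rc_seq <- dgrscan:::revcomp(sim$region$sequence)
  orf <- sim$rt_hit$orf
  rc_orf <- cds_feature(L - orf$end, L - orf$start, "-")
  rc_reg <- region_record("rc", rc_seq)
  rc_cass <- call_dgr(rc_reg, list(rt_hit("rc", rc_orf)), detection_params())
  expect_length(rc_cass, 1)
  expect_equal(rc_cass[[1]]$tr_span,
               c(L - cass$tr_span[2], L - cass$tr_span[1]))
  expect_equal(rc_cass[[1]]$vr_span,
               c(L - cass$vr_span[2], L - cass$vr_span[1]))
  expect_equal(rc_cass[[1]]$strand, "-")
  expect_equal(rc_cass[[1]]$adenine_mismatch_count, cass$adenine_mismatch_count)
})

test_that("motif_rt_scan flags long YxDD ORFs only", {
  # 350 aa ORF containing QGYADD
  body <- dgrscan:::rand_codons(344)
  orf <- paste0("ATG", substr(body, 1, 498), "CAAGGTTATGCCGATGAT",
                substr(body, 499, nchar(body)), "TAA")
  reg <- region_record("m", paste0(rand_seq(50), orf, rand_seq(50)),
                       features = list(cds_feature(50L, 50L + nchar(orf), "+")))
  hits <- motif_rt_scan(reg)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$source, "motif")

  # 100 aa ORF with the motif: rejected by the length filter
  small <- paste0("ATG", dgrscan:::rand_codons(40), "CAAGGTTATGCCGATGAT",
                  dgrscan:::rand_codons(51), "TAA")
  reg2 <- region_record("m2", small,
                        features = list(cds_feature(0L, nchar(small), "+")))
  expect_length(motif_rt_scan(reg2), 0)

  expect_length(motif_rt_scan(region_record("m3", rand_seq(500))), 0)
})
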