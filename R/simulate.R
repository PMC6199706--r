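# Mutagenic-retrohoming simulator: plants a ground-truth DGR cassette
# (RT ORF + invariant TR + diversified VR inside a target ORF) in a random
# genome, derives VRs by adenine-targeted substitution, and draws
# virome-like reads at controlled fold coverage and error rate. This is
# first-class, tested code: it defines the study conditions every other
# module is tested against.

#' Simulation parameters
#'
#' Defaults mirror the anatomy of the observed gut-phage cassette: a 117 bp
#' repeat with 30 template adenines, 14 of them substituted in the variable
#' copy, and virome-like 100 bp reads.
#'
#' @param seed RNG seed (every simulator output is a pure function of the
#'   parameters including this seed).
#' @param genome_len Genome length in bp.
#' @param tr_len Template-repeat length (bp).
#' @param tr_adenine_count Exact adenine count placed in the TR.
#' @param mutation_prob Per-adenine substitution probability used when
#'   `n_mismatches` is `NULL`.
#' @param n_mismatches Exact adenine-mismatch count to force (interior
#'   columns only, so planted boundaries have clean matching termini), or
#'   `NULL` for stochastic retrohoming at `mutation_prob`.
#' @param n_variants Number of VR variants for [sim_variants()] presets.
#' @param fold_coverage Read fold coverage for [synth_reads()] presets.
#' @param read_len Read length (bp).
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, genome_len = 6000L, tr_len = 117L,
                       tr_adenine_count = 30L, mutation_prob = 0.5,
                       n_mismatches = 14L, n_variants = 13L,
                       fold_coverage = 10, read_len = 100L,
                       error_rate = 0) {
  stopifnot(tr_adenine_count <= tr_len,
            mutation_prob >= 0, mutation_prob <= 1,
            error_rate >= 0, error_rate <= 1)
  if (!is.null(n_mismatches) && n_mismatches > tr_adenine_count)
    stop("sim_params: n_mismatches cannot exceed tr_adenine_count")
  structure(list(seed = as.integer(seed), genome_len = as.integer(genome_len),
                 tr_len = as.integer(tr_len),
                 tr_adenine_count = as.integer(tr_adenine_count),
                 mutation_prob = mutation_prob,
                 n_mismatches = if (is.null(n_mismatches)) NULL else
                   as.integer(n_mismatches),
                 n_variants = as.integer(n_variants),
                 fold_coverage = fold_coverage,
                 read_len = as.integer(read_len),
                 error_rate = error_rate),
            class = "sim_params")
}

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_codons <- function(n_codons) {
  sense <- setdiff(c(outer(c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                   paste0)), c("A", "C", "G", "T"), paste0)),
                   STOP_CODONS)
  paste(sample(sense, n_codons, TRUE), collapse = "")
}

has_inframe_stop <- function(orf_nt) {
  n <- nchar(orf_nt) %/% 3L
  codons <- substring(orf_nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  # ignore the terminal stop codon itself
  any(codons[-n] %in% STOP_CODONS)
}

#' Mutagenic retrohoming of a template repeat
#'
#' Each adenine of the TR is independently substituted, with probability
#' `mutation_prob`, by a base drawn uniformly from `{C,G,T}`; every
#' non-adenine position is copied verbatim. Drawing from the three
#' non-identical bases makes `mutation_prob` equal the realized mismatch
#' probability per adenine. Uses the ambient RNG stream; seed it with
#' `set.seed()` (or via [sim_params()]-driven wrappers) for reproducibility.
#'
#' @param tr TR DNA string over `{A,C,G,T}`.
#' @param mutation_prob Per-adenine substitution probability.
#' @return VR string of the same length.
#' @export
retrohome <- function(tr, mutation_prob) {
  chars <- strsplit(toupper(tr), "", fixed = TRUE)[[1]]
  a_pos <- which(chars == "A")
  if (length(a_pos)) {
    hit <- a_pos[runif(length(a_pos)) < mutation_prob]
    if (length(hit))
      chars[hit] <- sample(c("C", "G", "T"), length(hit), TRUE)
  }
  paste(chars, collapse = "")
}

# a TR with an exact adenine count; non-A positions uniform over {C,G,T}
make_tr <- function(tr_len, tr_adenine_count) {
  chars <- sample(c("C", "G", "T"), tr_len, TRUE)
  chars[sample.int(tr_len, tr_adenine_count)] <- "A"
  paste(chars, collapse = "")
}

# force exactly n adenine substitutions at interior columns
force_mismatches <- function(tr, n) {
  chars <- strsplit(tr, "", fixed = TRUE)[[1]]
  interior_a <- setdiff(which(chars == "A"), c(1L, length(chars)))
  if (length(interior_a) < n)
    stop("force_mismatches: not enough interior adenines")
  hit <- sample(interior_a, n)
  chars[hit] <- vapply(chars[hit], function(b)
    sample(setdiff(c("C", "G", "T"), b), 1L), "")
  paste(chars, collapse = "")
}

#' Plant a ground-truth DGR cassette in a random genome
#'
#' Builds a random genome containing, left to right: an RT ORF whose
#' translation carries the catalytic YxDD motif (>= 200 aa), the invariant
#' TR, and a target ORF with the VR embedded in frame near its 3' end. The
#' VR is derived from the TR by [retrohome()] (or by forcing exactly
#' `params$n_mismatches` interior adenine substitutions). The single base
#' flanking each repeat copy on either side is set to diverge between the
#' copies, so the planted boundaries are exactly recoverable, and the
#' construction is rejection-sampled so that no accidental duplication of
#' `min_repeat_len` bp or more exists outside the planted pair and the
#' target ORF stays free of in-frame stops.
#'
#' @param params A [sim_params()] object.
#' @param region_id Id for the generated region.
#' @param rt_len_aa RT ORF length in codons (>= 210).
#' @param target_pre_codons Codons of the target ORF upstream of the VR.
#' @param target_post_codons Codons between the VR and the stop codon.
#' @param spacer Intergenic spacer length (bp) used around the TR.
#' @param min_repeat_len Uniqueness guard: no accidental repeat of this
#'   length may survive outside the planted pair.
#' @param layout `"rt_first"` (RT ORF, TR, then target ORF left to right) or
#'   `"target_first"` (target ORF, TR, then RT ORF) — the latter keeps TR
#'   and VR adjacent even when the VR sits deep inside a very long target
#'   ORF, as in the gut-phage cassette.
#' @return List with `region` (a [region_record()] with RT and target CDS
#'   features), `rt_hit`, and `truth` (0-based `tr_span`, `vr_span`,
#'   `mismatch_columns`, TR/VR strings, target residue span).
#' @export
plant_cassette <- function(params = sim_params(), region_id = "sim_region",
                           rt_len_aa = 300L, target_pre_codons = 60L,
                           target_post_codons = 5L, spacer = 300L,
                           min_repeat_len = 40L,
                           layout = c("rt_first", "target_first")) {
  stopifnot(inherits(params, "sim_params"))
  layout <- match.arg(layout)
  if (params$tr_len %% 3L != 0L)
    stop("plant_cassette: tr_len must be a codon multiple for in-frame planting")
  with_seed(params$seed, {
    for (attempt in seq_len(200L)) {
      out <- try(plant_once(params, region_id, rt_len_aa, target_pre_codons,
                            target_post_codons, spacer, min_repeat_len,
                            layout),
                 silent = TRUE)
      if (!inherits(out, "try-error")) return(out)
    }
    stop("plant_cassette: could not satisfy constraints in 200 attempts ",
         "(geometry infeasible?)")
  })
}

plant_once <- function(params, region_id, rt_len_aa, target_pre_codons,
                       target_post_codons, spacer, min_repeat_len,
                       layout = "rt_first") {
  tr_codons <- params$tr_len %/% 3L
  rt_nt <- 3L * (rt_len_aa + 2L)                # ATG + codons + stop
  target_codons <- target_pre_codons + tr_codons + target_post_codons
  target_nt <- 3L * (target_codons + 2L)
  core <- rt_nt + spacer + params$tr_len + spacer + target_nt
  # the TR flanks are rewritten to diverge from the VR context over this
  # many columns; 45 > (max_mismatch_fraction * tr_len) / (1 - frac) for
  # the default geometry, so greedy extension can never coast past the
  # planted boundary on chance matches
  flank_div <- 45L
  if (spacer < flank_div || 3L * target_pre_codons < flank_div)
    stop("plant_cassette: spacer/pre-codon context too short for clean flanks")
  if (params$genome_len < core + 200L)
    stop("plant_cassette: genome_len too small for the requested geometry")

  # RT ORF: embed QGYADD so the translation matches [YFLIVM].DD
  motif_nt <- "CAAGGTTATGCCGATGAT"
  body <- rand_codons(rt_len_aa - 6L)
  ins <- 3L * sample.int(rt_len_aa - 6L, 1L)
  rt_orf <- paste0("ATG", substr(body, 1L, ins), motif_nt,
                   substr(body, ins + 1L, nchar(body)), "TAA")
  if (has_inframe_stop(rt_orf)) stop("stop in RT ORF")

  tr <- make_tr(params$tr_len, params$tr_adenine_count)
  vr <- if (is.null(params$n_mismatches)) retrohome(tr, params$mutation_prob)
        else force_mismatches(tr, params$n_mismatches)
  # clean termini: planted boundaries must be matching columns
  if (substr(tr, 1L, 1L) != substr(vr, 1L, 1L) ||
      substr(tr, params$tr_len, params$tr_len) !=
        substr(vr, params$tr_len, params$tr_len))
    stop("terminal mismatch")

  target_orf <- paste0("ATG", rand_codons(target_pre_codons), vr,
                       rand_codons(target_post_codons), "TAA")
  if (has_inframe_stop(target_orf)) stop("stop in target ORF")

  pad_total <- params$genome_len - core
  pad1 <- sample.int(pad_total - 100L, 1L)
  pad2 <- pad_total - pad1
  if (pad2 < flank_div) stop("right pad too short")

  # per-position divergent copy of a context string
  diverge <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(vapply(chars, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), ""), collapse = "")
  }

  vr_off_in_orf <- 3L + 3L * target_pre_codons  # VR offset within target ORF
  vr_left_ctx <- substr(target_orf, vr_off_in_orf - flank_div + 1L,
                        vr_off_in_orf)
  after_vr_in_orf <- substr(target_orf, vr_off_in_orf + params$tr_len + 1L,
                            nchar(target_orf))

  if (layout == "rt_first") {
    # [pad1][RT ORF][spacer1][TR][spacer2][target ORF][pad2]
    pad2_seq <- rand_dna(pad2)
    vr_right_ctx <- substr(paste0(after_vr_in_orf, pad2_seq), 1L, flank_div)
    # spacers around the TR: divergent from the VR's context columns
    spacer1 <- paste0(rand_dna(spacer - flank_div), diverge(vr_left_ctx))
    spacer2 <- paste0(diverge(vr_right_ctx), rand_dna(spacer - flank_div))
    genome <- paste0(rand_dna(pad1), rt_orf, spacer1, tr,
                     spacer2, target_orf, pad2_seq)
    rt_start <- pad1                             # 0-based
    rt_end <- rt_start + nchar(rt_orf)
    tr_start <- rt_end + spacer
    tr_end <- tr_start + params$tr_len
    target_start <- tr_end + spacer
    target_end <- target_start + nchar(target_orf)
    vr_start <- target_start + vr_off_in_orf
    vr_end <- vr_start + params$tr_len
  } else {
    # [pad1][target ORF][spacerA][TR][spacerB][RT ORF][pad2]
    spacerA_head <- rand_dna(spacer - flank_div)
    vr_right_ctx <- substr(paste0(after_vr_in_orf, spacerA_head), 1L,
                           flank_div)
    spacerA <- paste0(spacerA_head, diverge(vr_left_ctx))
    spacerB <- paste0(diverge(vr_right_ctx), rand_dna(spacer - flank_div))
    genome <- paste0(rand_dna(pad1), target_orf, spacerA, tr,
                     spacerB, rt_orf, rand_dna(pad2))
    target_start <- pad1
    target_end <- target_start + nchar(target_orf)
    vr_start <- target_start + vr_off_in_orf
    vr_end <- vr_start + params$tr_len
    tr_start <- target_end + spacer
    tr_end <- tr_start + params$tr_len
    rt_start <- tr_end + spacer
    rt_end <- rt_start + nchar(rt_orf)
  }

  # uniqueness guard: duplicated min_repeat_len-mers only within the pair
  n <- nchar(genome)
  starts <- seq_len(n - min_repeat_len + 1L)
  km <- substring(genome, starts, starts + min_repeat_len - 1L)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  in_pair <- (starts - 1L >= tr_start & starts - 1L + min_repeat_len <= tr_end) |
             (starts - 1L >= vr_start & starts - 1L + min_repeat_len <= vr_end)
  if (any(dup & !in_pair)) stop("accidental repeat in background")

  rt_feat <- cds_feature(rt_start, rt_end, "+",
                         product = "reverse transcriptase")
  target_feat <- cds_feature(target_start, target_end, "+",
                             product = "DGR target protein")
  region <- region_record(region_id, genome,
                          features = list(rt_feat, target_feat),
                          source = "simulated")
  mm <- which(strsplit(tr, "", fixed = TRUE)[[1]] !=
                strsplit(vr, "", fixed = TRUE)[[1]]) - 1L
  list(region = region,
       rt_hit = rt_hit(region_id, rt_feat, source = "motif"),
       truth = list(tr_span = c(tr_start, tr_end),
                    vr_span = c(vr_start, vr_end),
                    mismatch_columns = mm,
                    tr = tr, vr = vr,
                    target_residue_span = c(target_pre_codons + 2L,
                                            target_pre_codons + 1L + tr_codons)))
}

#' Simulate a variant set from one TR
#'
#' Draws `n_variants` independent VRs from the same TR by [retrohome()].
#'
#' @param tr TR DNA string.
#' @param n_variants Number of variants.
#' @param mutation_prob Per-adenine substitution probability.
#' @param seed RNG seed.
#' @param dgr_id Identifier for the [variant_set()].
#' @return A [variant_set()].
#' @export
sim_variants <- function(tr, n_variants, mutation_prob = 0.5, seed = 1L,
                         dgr_id = "sim_dgr") {
  with_seed(seed, {
    vrs <- setNames(
      lapply(seq_len(n_variants), function(i) retrohome(tr, mutation_prob)),
      sprintf("lysogen%02d", seq_len(n_variants)))
    variant_set(dgr_id, tr, vrs, reading_frame = list(offset = 0L, strand = "+"))
  })
}

#' Simulate virome-like reads from a region
#'
#' Draws `round(fold_coverage * region_len / read_len)` reads at uniform
#' random positions and strands, with independent per-base substitution
#' errors at `error_rate`.
#'
#' @param region A [region_record()].
#' @param fold_coverage Target mean fold coverage.
#' @param read_len Read length (bp), at most the region length.
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @return Named character vector of read sequences (names carry the true
#'   0-based start and strand, `<id>_<start>_<+/->`).
#' @export
synth_reads <- function(region, fold_coverage, read_len, error_rate = 0,
                        seed = 1L) {
  L <- nchar(region$sequence)
  if (read_len > L) stop("synth_reads: read_len exceeds region length")
  n <- round(fold_coverage * L / read_len)
  with_seed(seed, {
    starts <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    reads <- character(n)
    for (i in seq_len(n)) {
      s <- substr(region$sequence, starts[i] + 1L, starts[i] + read_len)
      if (strands[i] == "-") s <- revcomp(s)
      if (error_rate > 0) {
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        err <- which(runif(read_len) < error_rate)
        if (length(err))
          chars[err] <- vapply(chars[err], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        s <- paste(chars, collapse = "")
      }
      reads[i] <- s
    }
    setNames(reads, sprintf("%s_%d_%s", region$id, starts, strands))
  })
}
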