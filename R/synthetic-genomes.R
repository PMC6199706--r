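# Deterministic synthetic validation genomes.
#
# These are *synthetic analogs*, not the real sequences: each is a random
# genome constructed in code to reproduce the published anatomy of a known
# DGR-bearing phage, so the scanner's recovery of that anatomy can be
# verified offline and bit-reproducibly. They are clearly labelled
# synthetic and never stand in for the real records in any scientific
# claim beyond "a cassette with this geometry is recovered".

#' Synthetic Hankyphage-like genome
#'
#' A 42,831 bp synthetic genome with 45 CDS features emulating the
#' Hankyphage DGR anatomy: a reverse-transcriptase ORF, an invariant 117 bp
#' template repeat, and a variable repeat differing at exactly 14 template
#' adenines, embedded in frame near the C terminus of a large (2,232 codon)
#' target ORF so that the VR covers residues 2188-2226. The remaining 43
#' CDS are random filler ORFs. Fully deterministic (internal fixed seed).
#'
#' @return List with `region` (a [region_record()]), `rt_hit`, and `truth`
#'   (planted 0-based `tr_span`/`vr_span`, mismatch columns, repeat
#'   sequences, target residue span).
#' @export
synthetic_hankyphage <- function() {
  total_len <- 42831L
  prefix_len <- 20000L
  core_len <- 8769L
  suffix_len <- total_len - prefix_len - core_len

  core <- plant_cassette(
    sim_params(seed = 20180531L, genome_len = core_len, tr_len = 117L,
               tr_adenine_count = 30L, n_mismatches = 14L),
    region_id = "synthetic_hankyphage",
    rt_len_aa = 350L, target_pre_codons = 2186L, target_post_codons = 5L,
    spacer = 300L, layout = "target_first")

  with_seed(20180532L, {
    for (attempt in seq_len(50L)) {
      out <- try({
        pre <- filler_block(prefix_len, n_orfs = 25L)
        suf <- filler_block(suffix_len, n_orfs = 18L)
        assemble_synthetic(core, pre, suf, "synthetic_hankyphage")
      }, silent = TRUE)
      if (!inherits(out, "try-error")) return(out)
    }
    stop("synthetic_hankyphage: filler construction failed")
  })
}

#' Synthetic BPP-1-like genome
#'
#' A synthetic genome emulating the canonical Bordetella phage DGR: a
#' reverse-transcriptase ORF, a 134 bp template repeat, and a variable
#' repeat with 12 adenine mismatches spliced (frame-shifted, as the repeat
#' length is not a codon multiple) near the 3' end of a tail-fiber ORF
#' annotated "major tropism determinant (mtd), tail fiber". Deterministic.
#'
#' @return List with `region`, `rt_hit` and `truth` as in
#'   [synthetic_hankyphage()].
#' @export
synthetic_bpp1 <- function() {
  with_seed(20031201L, {
    for (attempt in seq_len(200L)) {
      out <- try(bpp1_once(), silent = TRUE)
      if (!inherits(out, "try-error")) return(out)
    }
    stop("synthetic_bpp1: construction failed")
  })
}

bpp1_once <- function() {
  tr_len <- 134L
  flank_div <- 60L
  spacer <- 300L
  rt_len_aa <- 320L

  motif_nt <- "CAAGGTTATGCCGATGAT"
  body <- rand_codons(rt_len_aa - 6L)
  ins <- 3L * sample.int(rt_len_aa - 6L, 1L)
  rt_orf <- paste0("ATG", substr(body, 1L, ins), motif_nt,
                   substr(body, ins + 1L, nchar(body)), "TAA")
  if (has_inframe_stop(rt_orf)) stop("stop in RT ORF")

  tr <- make_tr(tr_len, 34L)
  vr <- force_mismatches(tr, 12L)
  if (substr(tr, 1L, 1L) != substr(vr, 1L, 1L) ||
      substr(tr, tr_len, tr_len) != substr(vr, tr_len, tr_len))
    stop("terminal mismatch")

  # mtd ORF: 700 codons; splice the VR at a frame-shifted offset ending
  # 60 bp before the stop
  mtd_codons <- 700L
  mtd <- paste0("ATG", rand_codons(mtd_codons), "TAA")
  vr_off <- nchar(mtd) - 60L - tr_len - 2L       # not a multiple of 3
  mtd <- paste0(substr(mtd, 1L, vr_off), vr,
                substr(mtd, vr_off + tr_len + 1L, nchar(mtd)))
  if (has_inframe_stop(mtd)) stop("stop in mtd ORF")

  diverge <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(vapply(chars, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), ""), collapse = "")
  }
  vr_left_ctx <- substr(mtd, vr_off - flank_div + 1L, vr_off)
  vr_right_ctx <- substr(mtd, vr_off + tr_len + 1L,
                         vr_off + tr_len + flank_div)
  spacer1 <- paste0(rand_dna(spacer - flank_div), diverge(vr_left_ctx))
  spacer2 <- paste0(diverge(vr_right_ctx), rand_dna(spacer - flank_div))

  pad1 <- 400L; pad2 <- 400L
  genome <- paste0(rand_dna(pad1), rt_orf, spacer1, tr, spacer2, mtd,
                   rand_dna(pad2))

  rt_start <- pad1
  rt_end <- rt_start + nchar(rt_orf)
  tr_start <- rt_end + spacer
  tr_end <- tr_start + tr_len
  mtd_start <- tr_end + spacer
  mtd_end <- mtd_start + nchar(mtd)
  vr_start <- mtd_start + vr_off
  vr_end <- vr_start + tr_len

  n <- nchar(genome)
  starts <- seq_len(n - 40L + 1L)
  km <- substring(genome, starts, starts + 39L)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  in_pair <- (starts - 1L >= tr_start & starts - 1L + 40L <= tr_end) |
             (starts - 1L >= vr_start & starts - 1L + 40L <= vr_end)
  if (any(dup & !in_pair)) stop("accidental repeat")

  rt_feat <- cds_feature(rt_start, rt_end, "+",
                         product = "reverse transcriptase")
  mtd_feat <- cds_feature(mtd_start, mtd_end, "+",
                          product = "major tropism determinant (mtd), tail fiber")
  region <- region_record("synthetic_bpp1", genome,
                          features = list(rt_feat, mtd_feat),
                          source = "synthetic")
  mm <- which(strsplit(tr, "", fixed = TRUE)[[1]] !=
                strsplit(vr, "", fixed = TRUE)[[1]]) - 1L
  list(region = region,
       rt_hit = rt_hit("synthetic_bpp1", rt_feat, source = "motif"),
       truth = list(tr_span = c(tr_start, tr_end),
                    vr_span = c(vr_start, vr_end),
                    mismatch_columns = mm, tr = tr, vr = vr))
}

# a block of filler ORFs with intergenic spacers, exactly total_len bp
filler_block <- function(total_len, n_orfs) {
  codons <- sample(120:250, n_orfs, replace = TRUE)
  orf_nt <- 3L * (codons + 2L)
  min_spacer <- 80L
  leftover <- total_len - sum(orf_nt) - min_spacer * (n_orfs + 1L)
  if (leftover < 0L) stop("filler_block: ORFs do not fit")
  seq <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_len(n_orfs)) {
    sp <- min_spacer
    seq <- c(seq, rand_dna(sp)); pos <- pos + sp
    orf <- paste0("ATG", rand_codons(codons[i]), "TAA")
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") orf else revcomp(orf)
    feats[[i]] <- cds_feature(pos, pos + nchar(ins), strand,
                              product = "hypothetical protein")
    seq <- c(seq, ins); pos <- pos + nchar(ins)
  }
  seq <- c(seq, rand_dna(min_spacer + leftover))
  list(sequence = paste(seq, collapse = ""), features = feats)
}

assemble_synthetic <- function(core, pre, suf, id) {
  offset <- nchar(pre$sequence)
  genome <- paste0(pre$sequence, core$region$sequence, suf$sequence)
  shift <- function(f, by) cds_feature(f$start + by, f$end + by, f$strand,
                                       product = f$product,
                                       translation = f$translation)
  core_feats <- lapply(core$region$features, shift, by = offset)
  suf_off <- offset + nchar(core$region$sequence)
  feats <- c(pre$features, core_feats, lapply(suf$features, shift, by = suf_off))
  # order features by start coordinate, as an annotation pipeline would
  feats <- feats[order(vapply(feats, `[[`, 0L, "start"))]
  region <- region_record(id, genome, features = feats, source = "synthetic")
  rt_feat <- core_feats[[1L]]
  truth <- core$truth
  truth$tr_span <- truth$tr_span + offset
  truth$vr_span <- truth$vr_span + offset
  list(region = region, rt_hit = rt_hit(id, rt_feat, source = "motif"),
       truth = truth)
}
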