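test_that("read_fasta parses entries, normalizes case and alphabet", {
  f <- write_tmp(c(">r1 some description", "ACGTACGTAC"), ".fasta")
  r <- read_fasta(f)
  expect_length(r, 1)
  expect_equal(r[[1]]$id, "r1")
  expect_equal(nchar(r[[1]]$sequence), 10)

  f3 <- write_tmp(c(">a", "acgt", ">b", "GGGG", ">c", "TTTTT"), ".fasta")
  r3 <- read_fasta(f3)
  expect_equal(vapply(r3, `[[`, "", "id"), c("a", "b", "c"))
  expect_equal(r3[[1]]$sequence, "ACGT")

  fu <- write_tmp(c(">u", "ACGU"), ".fasta")
  expect_equal(read_fasta(fu)[[1]]$sequence, "ACGT")

  fbad <- write_tmp(c(">x", "ACRGT"), ".fasta")
  expect_warning(rx <- read_fasta(fbad), "non-ACGTN")
  expect_equal(rx[[1]]$sequence, "ACNGT")
})

test_that("read_fasta rejects empty files and duplicate ids", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")
  dup <- write_tmp(c(">a", "ACGT", ">a", "GGGG"), ".fasta")
  expect_error(read_fasta(dup), "duplicate")
})

test_that("read_genbank parses locations and converts coordinates", {
  f <- write_tmp(toy_genbank_lines(), ".gbk")
  r <- read_genbank(f)
  expect_equal(nchar(r$sequence), 60)
  expect_length(r$features, 2)
  # GenBank 1..9 (+) -> internal (0, 9, +)
  expect_equal(r$features[[1]]$start, 0L)
  expect_equal(r$features[[1]]$end, 9L)
  expect_equal(r$features[[1]]$strand, "+")
  expect_equal(r$features[[1]]$product, "tiny orf")
  # complement(20..40) -> (19, 40, -)
  expect_equal(r$features[[2]]$start, 19L)
  expect_equal(r$features[[2]]$end, 40L)
  expect_equal(r$features[[2]]$strand, "-")
})

test_that("read_genbank requires an ORIGIN block", {
  f <- write_tmp(c("LOCUS       x 10 bp", "FEATURES", "//"), ".gbk")
  expect_error(read_genbank(f), "ORIGIN")
})

test_that("GenBank writer round-trips sequence and CDS intervals exactly", {
  set.seed(42)
  for (i in 1:3) {
    n <- sample(200:400, 1)
    feats <- list(cds_feature(9L, 90L, "+", product = "alpha protein"),
                  cds_feature(120L, 150L, "-", product = "beta protein"))
    reg <- region_record(sprintf("round%d", i), rand_seq(n), features = feats)
    f <- tempfile(fileext = ".gbk")
    write_genbank(reg, f)
    back <- read_genbank(f)
    expect_equal(back$sequence, reg$sequence)
    expect_equal(lapply(back$features, function(x) x[c("start", "end", "strand")]),
                 lapply(reg$features, function(x) x[c("start", "end", "strand")]))
  }
})

test_that("1-based inclusive vs 0-based half-open conversion is a bijection", {
  set.seed(7)
  for (i in 1:50) {
    s0 <- sample(0:999, 1); e0 <- s0 + sample(1:500, 1)
    gb <- c(s0 + 1L, e0)                 # to GenBank
    back <- c(gb[1] - 1L, gb[2])         # and back
    expect_identical(back, c(s0, e0))
    expect_equal(gb[2] - gb[1] + 1L, e0 - s0)  # widths agree
  }
})

test_that("read_domtbl keeps only RT-domain rows and tolerates versions", {
  f <- write_tmp(c(
    "# comment line",
    domtbl_line("regA:1", "-", "RVT_1", "PF00078.17"),
    domtbl_line("regA:2", "-", "RVT_1", "PF00078"),
    domtbl_line("regA:3", "-", "Peptidase_S74", "PF13884.9"),
    "#"), ".domtbl")
  hits <- read_domtbl(f)
  expect_length(hits, 2)
  expect_equal(vapply(hits, `[[`, 0L, "orf_index"), c(1L, 2L))
  expect_equal(hits[[1]]$source, "domtbl")

  onlycomments <- write_tmp(c("# a", "# b"), ".domtbl")
  expect_length(read_domtbl(onlycomments), 0)
})

test_that("read_domtbl reports malformed rows with their line number", {
  f <- write_tmp(c(domtbl_line("r:1", "-", "RVT_1", "PF00078"),
                   "too few columns here"), ".domtbl")
  expect_error(read_domtbl(f), "line 2")
})

test_that("read_domtbl maps hits onto region ORFs by name", {
  reg <- region_record("regA", strrep("ACGT", 100),
                       features = list(cds_feature(0L, 99L, "+"),
                                       cds_feature(120L, 300L, "+")))
  f <- write_tmp(c(domtbl_line("regA:2", "-", "RVT_1", "PF00078"),
                   domtbl_line("regB:1", "-", "RVT_1", "PF00078")), ".domtbl")
  expect_warning(hits <- read_domtbl(f, regions = list(reg)), "regB")
  expect_length(hits, 1)
  expect_equal(hits[[1]]$orf$start, 120L)
})

test_that("cassette report converts coordinates and is byte-stable", {
  sim <- plant_cassette(sim_params(seed = 11, genome_len = 3000))
  cass <- call_dgr(sim$region, list(sim$rt_hit))
  expect_length(cass, 1)

  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_cassette_report(cass, f1, "tsv")
  write_cassette_report(cass, f2, "tsv")
  expect_identical(readLines(f1), readLines(f2))   # determinism

  df <- read.delim(f1)
  expect_equal(df$tr_start, sim$truth$tr_span[1] + 1L)  # 1-based inclusive
  expect_equal(df$tr_end, sim$truth$tr_span[2])
  expect_equal(df$vr_start, sim$truth$vr_span[1] + 1L)

  # empty report: header only
  f0 <- tempfile(fileext = ".tsv")
  write_cassette_report(list(), f0, "tsv")
  expect_length(readLines(f0), 1)

  # GFF3: three linked subfeatures per cassette
  fg <- tempfile(fileext = ".gff3")
  write_cassette_report(cass, fg, "gff3")
  g <- readLines(fg)
  expect_equal(g[1], "##gff-version 3")
  expect_equal(sum(grepl("Parent=dgr001", g)), 3)
  expect_true(any(grepl("Name=template_repeat", g)))
  expect_true(any(grepl("Name=variable_repeat", g)))
})

test_that("cds_translation uses the bacterial code and honors strand", {
  # forward: ATG GCC TAA -> MA (stop trimmed)
  reg <- region_record("t", "ATGGCCTAACGT",
                       features = list(cds_feature(0L, 9L, "+")))
  expect_equal(cds_translation(reg, reg$features[[1]]), "MA")
  # reverse strand: revcomp(ACGTTAGGCCAT) = ATGGCCTAACGT
  reg2 <- region_record("t2", "ACGTTAGGCCAT",
                        features = list(cds_feature(3L, 12L, "-")))
  expect_equal(cds_translation(reg2, reg2$features[[1]]), "MA")
  # stored /translation wins
  reg3 <- region_record("t3", "ATGGCCTAA",
                        features = list(cds_feature(0L, 9L, "+",
                                                    translation = "XY")))
  expect_equal(cds_translation(reg3, reg3$features[[1]]), "XY")
})
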