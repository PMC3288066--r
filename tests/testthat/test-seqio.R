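test_that("FASTA reading normalizes alphabets and validates records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "acgu", ">g2", "ACGT", "NNAC"), fa)
  utrs <- read_fasta(fa, "dna")
  expect_named(utrs, c("g1", "g2"))
  expect_equal(utrs$g1$sequence, "ACGT")      # U -> T, uppercased
  expect_equal(utrs$g2$sequence, "ACGTNNAC")  # wrapped lines joined
  expect_equal(utrs$g2$length, 8L)

  mirs <- local({
    mf <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">m1", "UGAGGUAGUAGGUUGUAUAGUU"), mf)
    read_fasta(mf, "rna")
  })
  expect_s3_class(mirs$m1, "mirna")
  expect_equal(nchar(mirs$m1$sequence), 22L)

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(read_fasta(empty, "dna"), 0L)

  dupf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dupf)
  expect_error(read_fasta(dupf, "dna"), "duplicate identifier 'a'")

  badf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACXT"), badf)
  expect_error(read_fasta(badf, "dna"), "illegal character 'X' at position 3")
})

test_that("dedupe_longest keeps the longest record per gene", {
  utrs <- list(utr_record("g1", "ACGT"), utr_record("g2", "AA"),
               utr_record("g1", "ACGTACGT"))
  out <- dedupe_longest(utrs)
  expect_equal(out$g1$length, 8L)
  expect_equal(out$g2$length, 2L)
})

test_that("MAF parsing keeps block structure and flags malformed rows", {
  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "",
               "a score=12.5",
               "s human.chr1 10 5 + 100 AC-GT",
               "s chimp.chr1 20 5 + 200 ACAGT",
               "s mouse.chr3  7 4 - 150 A--GT",
               "",
               "a score=1.0",
               "s human.chr1 30 3 + 100 GGG",
               "s chimp.chr1 40 3 + 200 GGG",
               ""), maf)
  blocks <- read_maf(maf)
  expect_length(blocks, 2L)
  expect_equal(nrow(blocks[[1]]$rows), 3L)   # missing species simply absent
  expect_equal(nrow(blocks[[2]]$rows), 2L)
  expect_equal(blocks[[1]]$score, 12.5)
  expect_equal(blocks[[1]]$rows$species, c("human", "chimp", "mouse"))
  expect_equal(blocks[[1]]$rows$start[1], 10L)   # 0-based starts kept as-is

  bad <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("a", "s human.chr1 ten 5 + 100 ACGTT"), bad)
  expect_error(read_maf(bad), "malformed 's' line at line 2")

  mismatch <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("a", "s human.chr1 0 4 + 10 ACGT",
               "s chimp.chr1 0 5 + 10 ACGTT", ""), mismatch)
  expect_error(read_maf(mismatch), "length mismatch")
})

test_that("stitching covers, pads and validates against the UTR", {
  utr <- utr_record("g1", "ACGTAC")
  blk <- list(score = 0, rows = data.frame(
    src = c("human.g1", "chimp.g1"), species = c("human", "chimp"),
    start = c(10L, 0L), size = c(6L, 6L), strand = "+",
    src_size = c(30L, 6L), text = c("ACGTAC", "ACGTCC"),
    stringsAsFactors = FALSE))
  aln <- stitch_aligned_utr(list(blk), utr, "human", c(10L, 16L), "chimp")
  expect_equal(unname(aln$rows["human"]), "ACGTAC")
  expect_equal(unname(aln$rows["chimp"]), "ACGTCC")

  # half-covered interval: uncovered reference positions become all-gap
  # columns for the other species, reference letters filled from the UTR
  blk2 <- blk
  blk2$rows$size <- 3L
  blk2$rows$text <- c("ACG", "ACG")
  aln2 <- stitch_aligned_utr(list(blk2), utr, "human", c(10L, 16L), "chimp")
  expect_equal(unname(aln2$rows["human"]), "ACGTAC")
  expect_equal(unname(aln2$rows["chimp"]), "ACG---")
  expect_equal(ungapped_ref(aln2), utr$sequence)

  # reverse-strand reference rows are flipped into + orientation:
  # stored rows are the reverse complements of the + strand alignment
  blk3 <- list(score = 0, rows = data.frame(
    src = c("human.g1", "chimp.g1"), species = c("human", "chimp"),
    start = c(14L, 0L), size = c(6L, 6L), strand = "-",
    src_size = c(30L, 6L),
    text = c("GTACGT", "GTACCT"), stringsAsFactors = FALSE))
  aln3 <- stitch_aligned_utr(list(blk3), utr, "human", c(10L, 16L), "chimp")
  expect_equal(unname(aln3$rows["human"]), "ACGTAC")
  expect_equal(unname(aln3$rows["chimp"]), "AGGTAC")

  # overlapping blocks on the reference are rejected
  expect_error(
    stitch_aligned_utr(list(blk, blk), utr, "human", c(10L, 16L), "chimp"),
    "overlapping")

  # mismatching reference sequence is caught
  expect_error(
    stitch_aligned_utr(list(blk), utr_record("g1", "TTTTTT"), "human",
                       c(10L, 16L), "chimp"),
    "disagrees")
})

test_that("stitching keeps insertion columns between retained positions", {
  utr <- utr_record("g1", "ACGT")
  blk <- list(score = 0, rows = data.frame(
    src = c("human.g1", "chimp.g1"), species = c("human", "chimp"),
    start = 0L, size = c(4L, 5L), strand = "+", src_size = c(4L, 5L),
    text = c("AC-GT", "ACAGT"), stringsAsFactors = FALSE))
  aln <- stitch_aligned_utr(list(blk), utr, "human", c(0L, 4L), "chimp")
  expect_equal(unname(aln$rows["human"]), "AC-GT")
  expect_equal(unname(aln$rows["chimp"]), "ACAGT")
  expect_equal(ungapped_ref(aln), "ACGT")
})

test_that("prediction TSV round-trips at printed precision", {
  scores <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                       t_filter = c(94L, 50L), c_filter = c(2L, 1L),
                       p_word = c(6.103516e-05, 1.234568e-04),
                       p_sh = c(1.5e-7, 3.2e-3), prediction = TRUE,
                       stringsAsFactors = FALSE)
  ranked <- rank_predictions(scores)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(ranked, f)
  back <- read_predictions(f)
  expect_equal(back$mirna_id, ranked$mirna_id)
  expect_equal(back$c_filter, ranked$c_filter)
  expect_equal(back$p_sh, ranked$p_sh, tolerance = 1e-6)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(back[, names(back) != "prediction"], f2)
  expect_identical(readLines(f), readLines(f2))

  fe <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(ranked[0, ], fe)
  expect_length(readLines(fe), 1L)   # header only
})
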