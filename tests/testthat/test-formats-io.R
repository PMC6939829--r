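test_that("FASTA parsing handles minimal, multi-line and lowercase records", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), p)
  a <- readFasta(p)
  expect_equal(contigNames(a), "c1")
  expect_equal(as.character(contigs(a)[[1]]), "ACGT")

  writeLines(c(">c1 extra description", "ac", "gt", ">c2", "NNN"), p)
  a <- readFasta(p)
  expect_equal(contigNames(a), c("c1", "c2"))
  expect_equal(unname(contigLengths(a)), c(4L, 3L))
  expect_equal(as.character(contigs(a)[[1]]), "ACGT")
})

test_that("FASTA rejects empty-sequence records and maps odd letters to N", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">bad", "", ">next", "AC"), p)
  expect_error(readFasta(p), "bad")

  writeLines(c(">amb", "ACRYGT"), p)
  a <- readFasta(p)
  expect_equal(as.character(contigs(a)[[1]]), "ACNNGT")
})

test_that("FASTA round-trip preserves 1,000 random records exactly", {
  set.seed(42)
  seqs <- setNames(vapply(sample(20:200, 1000, replace = TRUE),
                          randomDna, character(1)),
                   paste0("ctg", 1:1000))
  a <- Assembly("rt", seqs)
  p <- withr::local_tempfile(fileext = ".fa")
  writeFasta(a, p)
  b <- readFasta(p)
  expect_equal(contigNames(b), names(seqs))
  expect_equal(as.character(contigs(b)), seqs)
})

test_that("FASTQ parsing, gzip support and round-trip", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), p)
  r <- readFastq(p)
  expect_equal(names(r), "r1")
  expect_equal(Biostrings::width(r), 4L)
  expect_equal(as.character(S4Vectors::mcols(r)$qualities[[1]]), "IIII")

  file.create(p2 <- withr::local_tempfile(fileext = ".fastq"))
  expect_length(readFastq(p2), 0L)

  g <- simulateDiploid(simParams(genome_length = 2e4, seed = 5))
  lr <- simulateLongReads(g, coverage = 3,
                          longReadProfile(mean_length = 1200,
                                          error_range = c(0.1, 0.1)),
                          seed = 6)
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  writeFastq(lr$reads, gz)
  back <- readFastq(gz)
  expect_equal(names(back), names(lr$reads))
  expect_equal(as.character(back), as.character(lr$reads))
})

test_that("FASTQ quality/sequence length mismatch is a format error", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), p)
  expect_error(readFastq(p))
})

test_that("SAM parsing converts coordinates and honours the flag mix", {
  lines <- c(
    samLine("r1", 0, "c1", 1, "4M", "ACGT", "IIII", "NM:i:0"),
    samLine("r2", 4, "*", 0, "*"))
  p <- writeSamFixture(lines)
  aln <- readSam(p)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$target_start, 0L)
  expect_equal(aln$target_end, 4L)
  expect_equal(aln$edit_distance, 0L)
  expect_equal(attr(aln, "skipped_unmapped"), 1L)

  # 50 mapped records: 35 primary, 10 secondary, 5 supplementary
  flags <- c(rep(0, 35), rep(256, 10), rep(2048, 5))
  lines <- vapply(seq_along(flags), function(i)
    samLine(paste0("q", i), flags[i], "c1", 10, "5M", tags = "NM:i:0"),
    character(1))
  aln <- readSam(writeSamFixture(lines), primary_only = TRUE)
  expect_equal(nrow(aln), 40L)
  expect_equal(sum(aln$is_primary), 35L)
  expect_equal(sum(aln$is_supplementary), 5L)
  expect_equal(attr(aln, "dropped_secondary"), 10L)
})

test_that("SAM mismatch counts: =/X beats MD beats NM-minus-indels", {
  lines <- c(
    samLine("nm", 0, "c1", 1, "40M2D10M", tags = "NM:i:3"),
    samLine("md", 0, "c1", 1, "10M", tags = c("NM:i:2", "MD:Z:3A2^T3C0")),
    samLine("eqx", 0, "c1", 1, "3=1X6=", tags = "NM:i:1"))
  aln <- readSam(writeSamFixture(lines))
  expect_equal(aln$mismatches, c(1L, 2L, 1L))
  expect_equal(aln$del_bases, c(2L, 0L, 0L))
  expect_equal(aln$aligned_bases, c(50L, 10L, 10L))
})

test_that("missing mismatch evidence raises 'insufficient tags', never 0", {
  p <- writeSamFixture(samLine("r1", 0, "c1", 1, "10M"))
  aln <- readSam(p)
  expect_true(is.na(aln$mismatches))
  expect_error(readSam(p, require_mismatches = TRUE), "insufficient tags")
  expect_error(baseErrorRate(aln, reads_total = 1), "insufficient tags")
})

test_that("a mapped record without CIGAR is a format error", {
  p <- writeSamFixture(samLine("r1", 0, "c1", 1, "*"))
  expect_error(readSam(p), "CIGAR")
})

test_that("op-length sums reconcile with both coordinate spans", {
  g <- simulateDiploid(simParams(genome_length = 3e4, h_snv = 0.02, seed = 9))
  lr <- simulateLongReads(g, coverage = 2,
                          longReadProfile(mean_length = 3000,
                                          error_range = c(0.05, 0.05)),
                          seed = 10)
  aln <- mapReads(lr$reads, hapA(g))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(aln, sam, hapA(g))
  back <- readSam(sam)
  expect_gt(nrow(back), 0)
  for (i in seq_len(nrow(back))) {
    ops <- asmqc:::parseCigar(back$cigar[i])
    qcons <- sum(ops$len[ops$op %in% c("M", "I", "=", "X")])
    tcons <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
    expect_equal(qcons, back$query_end[i] - back$query_start[i])
    expect_equal(tcons, back$target_end[i] - back$target_start[i])
    expect_gt(back$query_end[i], back$query_start[i])
    expect_gt(back$target_end[i], back$target_start[i])
  }
  # the round trip preserves the counts the error rate depends on
  expect_equal(back$aligned_bases, aln$aligned_bases)
  expect_equal(back$mismatches, aln$mismatches)
  expect_equal(back$ins_bases, aln$ins_bases)
  expect_equal(back$del_bases, aln$del_bases)
})
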