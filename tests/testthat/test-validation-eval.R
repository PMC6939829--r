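test_that("base-level error rate decomposes CIGAR/NM arithmetic", {
  lines <- c(samLine("r1", 0, "c1", 1, "100M", tags = "NM:i:0"))
  aln <- readSam(writeSamFixture(lines))
  ms <- baseErrorRate(aln, reads_total = 1)
  expect_equal(errorRate(ms), 0)
  expect_equal(mappingRate(ms), 100)

  lines <- c(samLine("r1", 0, "c1", 1, "50M", tags = "NM:i:1"),
             samLine("r2", 0, "c1", 1, "50M", tags = "NM:i:0"))
  ms <- baseErrorRate(readSam(writeSamFixture(lines)), reads_total = 2)
  expect_equal(errorRate(ms), 0.01)

  lines <- samLine("r1", 0, "c1", 1, "40M2D10M", tags = "NM:i:3")
  ms <- baseErrorRate(readSam(writeSamFixture(lines)), reads_total = 1)
  expect_equal(errorRate(ms), 3 / 50)  # 1 mismatch + 2 deleted over 50
  expect_equal(ms@mismatchBases, 1)
  expect_equal(ms@deletedBases, 2)
})

test_that("only primary alignments count toward the error rate", {
  lines <- c(samLine("r1", 0, "c1", 1, "50M", tags = "NM:i:0"),
             samLine("r1", 2048, "c1", 100, "25M", tags = "NM:i:25"))
  ms <- baseErrorRate(readSam(writeSamFixture(lines)), reads_total = 1)
  expect_equal(errorRate(ms), 0)
  expect_equal(ms@alignedBases, 50)
})

test_that("the theoretical error floor is tech error plus half h", {
  expect_equal(errorFloor(theoreticalMinError(0.003, 0.015)), 0.0105)
  expect_equal(errorFloor(theoreticalMinError(0, 0)), 0)
  expect_equal(errorFloor(theoreticalMinError(0.10, 0.02)), 0.11)
  expect_error(theoreticalMinError(-0.1, 0))
  expect_error(theoreticalMinError(0, 1.5))
})

mkAln <- function(qid, contig = "c1", tstart = 0, cigar = "100M",
                  strand = "+", primary = TRUE, suppl = FALSE,
                  qstart = 0) {
  ops <- asmqc:::parseCigar(cigar)
  s <- asmqc:::cigarOpSums(ops)
  data.frame(query_id = qid, flag = 0L, target_id = contig,
             target_start = tstart, target_end = tstart + s$aligned + s$del,
             strand = strand, query_len = s$aligned + s$ins + s$clip,
             query_start = qstart, query_end = qstart + s$aligned + s$ins,
             is_primary = primary, is_supplementary = suppl, cigar = cigar,
             aligned_bases = s$aligned, mismatches = 0L, ins_bases = s$ins,
             del_bases = s$del, clip_bases = s$clip,
             edit_distance = s$ins + s$del, stringsAsFactors = FALSE)
}

test_that("clustered deletions need >= min_support distinct reads", {
  set.seed(51)
  mk <- function(n) do.call(rbind, lapply(seq_len(n), function(i)
    mkAln(paste0("r", i), tstart = 5000 + sample(-25:25, 1),
          cigar = "500M200D500M")))
  ev12 <- detectSV(mk(12))
  expect_equal(nrow(ev12), 1L)
  expect_equal(ev12$type, "DEL")
  expect_equal(ev12$support, 12L)
  expect_lt(abs(ev12$length - 200), 1)
  expect_lt(abs(ev12$position - 5500), 50)

  expect_equal(nrow(detectSV(mk(9))), 0L)  # below the >=10-read rule
  expect_equal(nrow(detectSV(mkAln("r1")[0, ])), 0L)  # empty stream
})

test_that("split reads on different contigs yield translocations", {
  aln <- do.call(rbind, lapply(1:11, function(i) rbind(
    mkAln(paste0("r", i), contig = "c1", tstart = 900, cigar = "400M600S"),
    mkAln(paste0("r", i), contig = "c2", tstart = 0, cigar = "400S600M",
          suppl = TRUE, primary = FALSE, qstart = 400))))
  ev <- detectSV(aln)
  expect_equal(ev$type, "TRA")
  expect_equal(ev$contig, "c1")
  expect_equal(ev$support, 11L)
})

test_that("split reads with a reference gap yield a deletion call", {
  aln <- do.call(rbind, lapply(1:10, function(i) rbind(
    mkAln(paste0("r", i), tstart = 1000, cigar = "300M300S"),
    mkAln(paste0("r", i), tstart = 1800, cigar = "300S300M",
          suppl = TRUE, primary = FALSE, qstart = 300))))
  ev <- detectSV(aln)
  expect_equal(ev$type, "DEL")
  expect_equal(ev$length, 500)
  expect_equal(ev$position, 1300)
})

test_that("lowering min_support never loses events", {
  set.seed(52)
  aln <- rbind(
    do.call(rbind, lapply(1:12, function(i)
      mkAln(paste0("a", i), tstart = 2000, cigar = "100M80D100M"))),
    do.call(rbind, lapply(1:6, function(i)
      mkAln(paste0("b", i), tstart = 9000, cigar = "100M120I100M"))))
  n10 <- nrow(detectSV(aln, min_support = 10))
  n5 <- nrow(detectSV(aln, min_support = 5))
  n1 <- nrow(detectSV(aln, min_support = 1))
  expect_equal(n10, 1L)
  expect_equal(n5, 2L)
  expect_gte(n5, n10)
  expect_gte(n1, n5)
})

test_that("sv summaries total the event multiset", {
  ev <- data.frame(type = c("INS", "INS", "DEL"), contig = "c1",
                   position = c(1, 2, 3), length = 60, support = 12)
  s <- svSummary(ev)
  expect_equal(s$INS, 2)
  expect_equal(s$DEL, 1)
  expect_equal(s$TRA, 0)
  expect_equal(s$total, 3)
  s0 <- svSummary(ev[0, ])
  expect_equal(unlist(s0), c(INS = 0, DEL = 0, TRA = 0, total = 0))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeSvEvents(ev, p)
  expect_equal(nrow(read.delim(p)), 3L)
})

test_that("error-free reads map perfectly back to their source", {
  g <- simulateDiploid(simParams(genome_length = 4e4, repeat_fraction = 0,
                                 h_snv = 0, h_indel = 0, seed = 53))
  lr <- simulateLongReads(g, coverage = 5,
                          longReadProfile(mean_length = 4000,
                                          error_range = c(0, 0)),
                          seed = 54)
  aln <- mapReads(lr$reads, hapA(g))
  ms <- baseErrorRate(aln, reads_total = length(lr$reads))
  expect_equal(errorRate(ms), 0)
  expect_equal(mappingRate(ms), 100)
  expect_equal(nrow(detectSV(aln, min_support = 1)), 0L)
})

test_that("misjoined contigs surface as split-read clusters at junctions", {
  g <- simulateDiploid(simParams(genome_length = rep(3e4, 6),
                                 repeat_fraction = 0, h_snv = 0,
                                 h_indel = 0, seed = 55))
  corr <- corruptAssembly(hapA(g), spec = list(misjoins = 3), seed = 56)
  lr <- simulateLongReads(g, coverage = 20,
                          longReadProfile(mean_length = 5000,
                                          error_range = c(0, 0)),
                          seed = 57, haplotypes = "A")
  aln <- mapReads(lr$reads, corr$assembly)
  ev <- detectSV(aln, min_support = 10)
  expect_gte(sum(ev$type %in% c("TRA", "DEL")), 3L)
})
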