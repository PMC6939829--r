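test_that("zero heterozygosity collapses the haplotypes", {
  g <- simulateDiploid(simParams(genome_length = 2e4, h_snv = 0,
                                 h_indel = 0, seed = 61))
  expect_equal(as.character(contigs(hapA(g))), as.character(contigs(hapB(g))))
  expect_equal(nrow(simTruth(g)$snv), 0L)
})

test_that("realised SNV divergence sits inside the binomial 3-sigma band", {
  g <- simulateDiploid(simParams(genome_length = 1e5, h_snv = 0.01,
                                 h_indel = 0, repeat_fraction = 0,
                                 seed = 62))
  rate <- nrow(simTruth(g)$snv) / 1e5
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 1e5))
  # haplotype B is derivable from A by the truth set: spot-check SNVs
  tr <- simTruth(g)$snv
  a <- as.character(contigs(hapA(g))[[1]])
  for (i in sample(nrow(tr), 25))
    expect_equal(substr(a, tr$pos[i] + 1, tr$pos[i] + 1), tr$ref[i])
})

test_that("simulators are byte-identical under a fixed seed", {
  p <- simParams(genome_length = 3e4, seed = 63)
  g1 <- simulateDiploid(p)
  g2 <- simulateDiploid(p)
  expect_identical(as.character(contigs(hapA(g1))),
                   as.character(contigs(hapA(g2))))
  expect_identical(simTruth(g1), simTruth(g2))
  r1 <- simulateLongReads(g1, 3, longReadProfile(mean_length = 2000),
                          seed = 64)
  r2 <- simulateLongReads(g1, 3, longReadProfile(mean_length = 2000),
                          seed = 64)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  expect_identical(r1$truth, r2$truth)
  r3 <- simulateLongReads(g1, 3, longReadProfile(mean_length = 2000),
                          seed = 65)
  expect_false(identical(as.character(r3$reads), as.character(r1$reads)))
})

test_that("long-read totals hit the requested coverage", {
  g <- simulateDiploid(simParams(genome_length = 1e5, seed = 66))
  lr <- simulateLongReads(g, 20, longReadProfile(error_range = c(0, 0)),
                          seed = 67)
  total <- sum(Biostrings::width(lr$reads))
  expect_lte(abs(total - 20 * 1e5) / (20 * 1e5), 0.02)
  expect_true(all(Biostrings::width(lr$reads) <= 1e5))
})

test_that("error-free long reads are exact substrings of a haplotype", {
  g <- simulateDiploid(simParams(genome_length = 5e4, seed = 68))
  lr <- simulateLongReads(g, 2, longReadProfile(mean_length = 3000,
                                                error_range = c(0, 0)),
                          seed = 69)
  haps <- list(A = hapA(g), B = hapB(g))
  for (i in seq_len(nrow(lr$truth))) {
    tr <- lr$truth[i, ]
    src <- substr(as.character(contigs(haps[[tr$haplotype]])[[tr$contig]]),
                  tr$start + 1, tr$end)
    got <- as.character(lr$reads[[tr$read]])
    if (tr$strand == "-") got <- revcomp(got)
    expect_identical(got, src)
  }
})

test_that("realised long-read error matches the requested rate", {
  g <- simulateDiploid(simParams(genome_length = 5e4, repeat_fraction = 0,
                                 seed = 70))
  lr <- simulateLongReads(g, 2, longReadProfile(mean_length = 2500,
                                                error_range = c(0.12, 0.12)),
                          seed = 71)
  haps <- list(A = hapA(g), B = hapB(g))
  idx <- which(lr$truth$end - lr$truth$start <= 4000)[1:15]
  rates <- vapply(idx, function(i) {
    tr <- lr$truth[i, ]
    src <- substr(as.character(contigs(haps[[tr$haplotype]])[[tr$contig]]),
                  tr$start + 1, tr$end)
    got <- as.character(lr$reads[[tr$read]])
    if (tr$strand == "-") got <- revcomp(got)
    mat <- Biostrings::nucleotideSubstitutionMatrix(0, -1, baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(got, src, substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1)
    -Biostrings::score(aln) / (tr$end - tr$start)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.12), 0.01)
})

test_that("short-read pairs respect insert geometry and coverage", {
  g <- simulateDiploid(simParams(genome_length = 1e5, seed = 72))
  sr <- simulateShortReads(g, 5, seed = 73)
  expect_equal(length(sr$reads) %% 2, 0)
  expect_true(all(Biostrings::width(sr$reads) == 150))
  total <- sum(Biostrings::width(sr$reads))
  expect_lte(abs(total - 5e5) / 5e5, 0.02)
  ins <- sr$truth$end - sr$truth$start
  expect_lt(abs(mean(ins) - 400), 10)  # mean insert 400 +/- sampling noise
  # inner gap between mates averages insert - 2 x read length = 100
  expect_lt(abs(mean(ins - 300) - 100), 10)
  # mates are revcomp-consistent with the fragment (error-free profile)
  sr <- simulateShortReads(g, 0.5, shortReadProfile(error_rate = 0),
                           seed = 73)
  tr <- sr$truth[1, ]
  frag <- substr(as.character(contigs(
    (if (tr$haplotype == "A") hapA(g) else hapB(g)))[[tr$contig]]),
    tr$start + 1, tr$end)
  expect_equal(as.character(sr$reads[[paste0(tr$read, "/1")]]),
               substr(frag, 1, 150))
  expect_equal(as.character(sr$reads[[paste0(tr$read, "/2")]]),
               revcomp(substr(frag, nchar(frag) - 149, nchar(frag))))
})

test_that("corruptAssembly plants exactly what its manifest says", {
  g <- simulateDiploid(simParams(genome_length = rep(2e4, 4), seed = 74))
  none <- corruptAssembly(hapA(g), spec = list(), seed = 75)
  expect_equal(as.character(contigs(none$assembly)),
               as.character(contigs(hapA(g))))

  corr <- corruptAssembly(hapA(g),
                          spec = list(haplotig_duplications = 2,
                                      misjoins = 1, indel_errors = 3),
                          seed = 76)
  man <- corr$manifest
  expect_equal(nrow(man$haplotigs), 2L)
  expect_equal(nrow(man$misjoins), 1L)
  expect_equal(nrow(man$indels), 3L)
  expect_true(all(man$haplotigs$new_id %in% contigNames(corr$assembly)))
  # a reciprocal tail swap alone preserves total length
  mj <- corruptAssembly(hapA(g), spec = list(misjoins = 2), seed = 77)
  expect_equal(totalLength(mj$assembly), totalLength(hapA(g)))
})

test_that("SV specs are applied exactly and rejected when inconsistent", {
  sv <- data.frame(type = c("DEL", "INS"), contig = "chr01",
                   position = c(10000, 30000), length = c(300, 200))
  g <- simulateDiploid(simParams(genome_length = 5e4, h_snv = 0,
                                 h_indel = 0, repeat_fraction = 0,
                                 sv_spec = sv, seed = 77))
  expect_equal(totalLength(hapB(g)), 5e4 - 300 + 200)
  expect_equal(nrow(simTruth(g)$sv), 2L)

  bad <- data.frame(type = c("DEL", "DEL"), contig = "chr01",
                    position = c(10000, 10100), length = c(300, 300))
  expect_error(simulateDiploid(simParams(genome_length = 5e4, sv_spec = bad,
                                         seed = 78)), "sv_spec")
})

test_that("truth tables serialise to plain text", {
  g <- simulateDiploid(simParams(genome_length = 2e4, seed = 79))
  d <- withr::local_tempdir()
  paths <- writeSimTruth(g, d)
  expect_true(all(file.exists(paths)))
  v <- read.delim(paths[1])
  expect_equal(sum(v$class == "SNV"), nrow(simTruth(g)$snv))
})
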