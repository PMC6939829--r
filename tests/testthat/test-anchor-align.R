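test_that("self-anchors reconstruct the full diagonal", {
  set.seed(5)
  s <- randomDna(2000)
  a <- seedAnchors(s, s, seed_k = 15)
  expect_true(any(a$qstart == 0 & a$tstart == 0 & a$len == 2000 &
                    a$strand == "+"))
})

test_that("a reverse-complemented query anchors only on the minus strand", {
  set.seed(6)
  t <- randomDna(1500)
  a <- seedAnchors(revcomp(t), t, seed_k = 15)
  expect_gt(nrow(a), 0)
  expect_true(all(a$strand == "-"))
  # every anchor verifies as an exact match in the '-' sense
  q <- revcomp(t)
  for (i in seq_len(min(nrow(a), 10))) {
    qs <- substr(q, a$qstart[i] + 1, a$qstart[i] + a$len[i])
    ts <- substr(t, a$tstart[i] + 1, a$tstart[i] + a$len[i])
    expect_equal(revcomp(qs), ts)
  }
})

test_that("a planted shared segment is the only anchor source", {
  set.seed(7)
  seg <- randomDna(100)
  q <- paste0(randomDna(2400), seg, randomDna(2500))
  t <- paste0(randomDna(1000), seg, randomDna(3900))
  a <- seedAnchors(q, t, seed_k = 15)
  expect_gt(nrow(a), 0)
  expect_true(all(a$qstart >= 2400 & a$qstart + a$len <= 2500))
  expect_true(all(a$tstart >= 1000 & a$tstart + a$len <= 1100))
})

test_that("identical sequences give one perfect full-length block", {
  set.seed(8)
  s <- randomDna(2000)
  b <- chainAndExtend(s, s)
  expect_equal(nrow(b), 1L)
  expect_equal(b$identity, 100)
  expect_equal(c(b$qstart, b$qend, b$tstart, b$tend), c(0, 2000, 0, 2000))
})

test_that("one substitution per 100 bp yields ~99% identity", {
  set.seed(9)
  s <- randomDna(2000)
  ch <- strsplit(s, "")[[1]]
  pos <- seq(50, 1950, by = 100)  # 20 substitutions, ends intact
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  b <- chainAndExtend(paste(ch, collapse = ""), s)
  expect_equal(nrow(b), 1L)
  expect_lt(abs(b$identity - 99), 0.1)
})

test_that("block identity matches the full-DP oracle on small instances", {
  set.seed(10)
  params <- alignParams(min_block_len = 50L)
  for (i in 1:40) {
    n <- sample(80:200, 1)
    t <- randomDna(n)
    ch <- strsplit(t, "")[[1]]
    nmut <- rbinom(1, n - 40, 0.05)
    if (nmut > 0) {
      # interior edits only, so anchors reach both ends and the block
      # covers the same span as the global DP
      pos <- sample(21:(n - 20), nmut)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      ndel <- rbinom(1, 1, 0.3)
      if (ndel && nmut >= 2) ch[pos[1]] <- ""
    }
    q <- paste(ch, collapse = "")
    b <- chainAndExtend(q, t, params)
    expect_equal(nrow(b), 1L)
    expect_lt(abs(b$identity - dpIdentity(q, t)), 0.5)
  }
})

test_that("whole-assembly similarity behaves under planted divergence", {
  g <- simulateDiploid(simParams(genome_length = c(2e4, 2e4),
                                 repeat_fraction = 0, h_snv = 0.02,
                                 h_indel = 0, seed = 21))
  A <- hapA(g)
  # self-alignment covers everything
  expect_equal(coverageFraction(
    referenceCoverage(alignAssemblies(A, A), A)), 1.0)
  # 2% divergence: near-complete at identity 75, near-zero at identity 99
  B <- hapB(g)
  cov75 <- coverageFraction(referenceCoverage(
    alignAssemblies(B, A, min_identity = 75), A))
  cov99 <- coverageFraction(referenceCoverage(
    alignAssemblies(B, A, min_identity = 99), A))
  expect_gt(cov75, 0.98)
  expect_lt(cov99, 0.05)
})

test_that("aligning half a contig covers half the reference", {
  set.seed(22)
  s <- randomDna(30000)
  A <- Assembly("A", c(c1 = s))
  B <- Assembly("B", c(h1 = substr(s, 1, 15000)))
  cov <- referenceCoverage(alignAssemblies(B, A), A)
  expect_lt(abs(coverageFraction(cov) - 0.5), 0.01)
})

test_that("merged coverage handles overlaps, emptiness and bounds", {
  ref <- Assembly("ref", c(c1 = strrep("A", 1000)))
  blocks <- data.frame(query_id = "q", target_id = "c1",
                       qstart = 0, qend = 100, tstart = c(0, 50),
                       tend = c(100, 150), strand = "+", matches = 100,
                       mismatches = 0, ins = 0, del = 0,
                       aligned_length = 100, identity = 100)
  cov <- referenceCoverage(blocks, ref)
  expect_equal(cov@coveredBases, 150)
  expect_equal(coverageFraction(cov), 0.15)
  expect_equal(coverageFraction(referenceCoverage(blocks[0, ], ref)), 0)
  bad <- blocks; bad$tend <- 2000
  expect_error(referenceCoverage(bad, ref), "bounds")
})

test_that("random block sets match per-base coverage oracles exactly", {
  set.seed(23)
  lens <- c(c1 = 3500L, c2 = 2000L)
  ref <- Assembly("ref", vapply(lens, function(l) strrep("A", l),
                                character(1)))
  for (rep in 1:5) {
    n <- 30
    cn <- sample(names(lens), n, replace = TRUE)
    st <- vapply(cn, function(x) sample.int(lens[[x]] - 10, 1), numeric(1))
    en <- pmin(st + sample(5:800, n, replace = TRUE), lens[cn])
    blocks <- data.frame(query_id = "q", target_id = cn, qstart = 0,
                         qend = en - st, tstart = st, tend = en,
                         strand = "+", matches = en - st, mismatches = 0,
                         ins = 0, del = 0, aligned_length = en - st,
                         identity = 100)
    cov <- referenceCoverage(blocks, ref)
    expect_equal(cov@coveredBases, bruteCoverage(blocks, lens))
    bc <- binnedCoverage(blocks, ref, bin_size = 1000)
    expect_equal(bc$value, bruteBinned(blocks, lens, 1000))
    # merged coverage never exceeds multi-counted coverage
    expect_lte(cov@coveredBases, sum(as.numeric(en - st)))
  }
})

test_that("binned coverage multi-counts and normalises the partial bin", {
  ref <- Assembly("ref", c(c1 = strrep("A", 2500)))
  blk <- function(s, e) data.frame(query_id = "q", target_id = "c1",
                                   qstart = 0, qend = e - s, tstart = s,
                                   tend = e, strand = "+", matches = e - s,
                                   mismatches = 0, ins = 0, del = 0,
                                   aligned_length = e - s, identity = 100)
  one <- binnedCoverage(blk(0, 1000), ref, bin_size = 1000)
  expect_equal(one$value, c(1, 0, 0))
  two <- binnedCoverage(rbind(blk(0, 1000), blk(0, 1000)), ref,
                        bin_size = 1000)
  expect_equal(two$value[1], 2)  # counted twice, not merged
  part <- binnedCoverage(blk(2000, 2500), ref, bin_size = 1000)
  expect_equal(part$value, c(0, 0, 1))  # 500/500, true bin length
})

test_that("strand symmetry: reverse-complementing the query reflects blocks", {
  set.seed(24)
  t <- randomDna(3000)
  q <- substr(t, 501, 2500)
  bf <- chainAndExtend(q, t)
  br <- chainAndExtend(revcomp(q), t)
  expect_equal(nrow(bf), 1L)
  expect_equal(nrow(br), 1L)
  expect_equal(br$strand, "-")
  expect_equal(br$identity, bf$identity)
  expect_equal(br$tstart, bf$tstart)
  expect_equal(br$tend, bf$tend)
  expect_equal(br$qstart, nchar(q) - bf$qend)
  expect_equal(br$qend, nchar(q) - bf$qstart)
})

test_that("marker mapping: exact hits, divergence floor, planted truth", {
  set.seed(25)
  ctg <- randomDna(8000)
  asm <- Assembly("a", c(c1 = ctg))
  m <- substr(ctg, 3001, 3500)
  hits <- mapMarkers(c(m1 = m), asm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 100)
  expect_equal(hits$tstart, 3000)

  # ~40% diverged marker finds nothing at an 80% identity floor
  ch <- strsplit(m, "")[[1]]
  pos <- sample(seq_along(ch), 200)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  expect_equal(nrow(mapMarkers(c(bad = paste(ch, collapse = "")), asm)), 0L)

  # planted markers across a multi-contig assembly: exactly the planted set
  g <- simulateDiploid(simParams(genome_length = rep(1e4, 5),
                                 repeat_fraction = 0, seed = 26))
  seqs <- as.character(contigs(hapA(g)))
  markers <- unlist(lapply(names(seqs), function(cn)
    setNames(lapply(c(1000, 5000), function(o)
      substr(seqs[[cn]], o, o + 399)),
      paste0(cn, "_m", c(1, 2)))))
  hits <- mapMarkers(markers, hapA(g))
  got <- sort(paste(hits$marker_id, hits$contig_id))
  want <- sort(paste(names(markers), rep(names(seqs), each = 2)))
  expect_equal(got, want)
})
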