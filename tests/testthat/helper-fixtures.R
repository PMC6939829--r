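# Shared fixtures and independent oracles, all built in code.

options(asmqc.verbose = FALSE)

randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# write a SAM file from raw field lists
writeSamFixture <- function(lines, sq = c(c1 = 1000L)) {
  path <- withr::local_tempfile(fileext = ".sam",
                                .local_envir = parent.frame())
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, lines), path)
  path
}

samLine <- function(qname, flag, rname, pos, cigar, seq = "*", qual = "*",
                    tags = character(0)) {
  paste(c(qname, flag, rname, pos, 60, cigar, "*", 0, 0, seq, qual, tags),
        collapse = "\t")
}

# independent N50 oracle: scan length thresholds descending
bruteN50 <- function(lens) {
  total <- sum(lens)
  for (x in sort(unique(lens), decreasing = TRUE))
    if (sum(lens[lens >= x]) >= total / 2) return(x)
}

bruteL50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  acc <- 0
  for (i in seq_along(lens)) {
    acc <- acc + lens[i]
    if (acc >= sum(lens) / 2) return(i)
  }
}

# per-base merged coverage oracle
bruteCoverage <- function(blocks, lens) {
  covered <- 0
  for (cn in names(lens)) {
    hit <- logical(lens[[cn]])
    b <- blocks[blocks$target_id == cn, , drop = FALSE]
    for (i in seq_len(nrow(b)))
      hit[(b$tstart[i] + 1):b$tend[i]] <- TRUE
    covered <- covered + sum(hit)
  }
  covered
}

# per-base multi-counted binned coverage oracle
bruteBinned <- function(blocks, lens, bin_size) {
  out <- list()
  for (cn in names(lens)) {
    depth <- numeric(lens[[cn]])
    b <- blocks[blocks$target_id == cn, , drop = FALSE]
    for (i in seq_len(nrow(b)))
      depth[(b$tstart[i] + 1):b$tend[i]] <-
        depth[(b$tstart[i] + 1):b$tend[i]] + 1
    starts <- seq(0, lens[[cn]] - 1, by = bin_size)
    ends <- pmin(starts + bin_size, lens[[cn]])
    out[[cn]] <- vapply(seq_along(starts), function(j)
      sum(depth[(starts[j] + 1):ends[j]]) / (ends[j] - starts[j]), numeric(1))
  }
  unlist(out, use.names = FALSE)
}

# full-DP identity oracle via Biostrings (scoring matched to the package's
# gap-closure kernel: match 2, mismatch -4, linear gap -4)
dpIdentity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 4,
                                       type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  100 * sum(p == s & p != "-") / length(p)
}

# a small diploid genome + planted-haplotig assembly + markers, used by the
# GCICA tests and acceptance checks
plantedHaplotigCase <- function(seed, n_contigs = 8, contig_len = 12000,
                                n_haplotigs = 3, identity = 0.98) {
  g <- simulateDiploid(simParams(genome_length = rep(contig_len, n_contigs),
                                 repeat_fraction = 0, h_snv = 0.01,
                                 seed = seed))
  corr <- corruptAssembly(hapA(g),
                          spec = list(haplotig_duplications = n_haplotigs,
                                      haplotig_identity = identity),
                          seed = seed + 1000L)
  seqs <- as.character(contigs(hapA(g)))
  marker_list <- list()
  for (cn in names(seqs)) {
    for (k in 1:4) {
      off <- 1000L + (k - 1L) * 2500L
      marker_list[[sprintf("%s_m%d", cn, k)]] <-
        substr(seqs[[cn]], off, off + 399L)
    }
  }
  list(genome = g, assembly = corr$assembly, manifest = corr$manifest,
       markers = unlist(marker_list))
}
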