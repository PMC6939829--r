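# Synthetic diploid genomes, long/short reads with realistic error
# profiles, and assemblies with planted defects. Every stochastic step is
# a pure function of (parameters, seed), so fixtures are generated at test
# time and identical seeds give identical bytes.

#' Simulation parameter sets
#'
#' `simParams()` describes the diploid genome: per-contig lengths, GC
#' content, a dispersed near-identical repeat family, per-base SNV and
#' small-indel heterozygosity between the two haplotypes, and optional
#' structural variants. Defaults emulate a heterozygous tree genome in
#' miniature: 1.5% SNV heterozygosity and ~39% GC, with a tenth of the
#' sequence in dispersed repeats.
#'
#' @param genome_length numeric vector of contig lengths (one contig per
#'   element).
#' @param gc GC fraction.
#' @param repeat_fraction fraction of each contig occupied by planted
#'   repeat copies.
#' @param repeat_unit_len repeat monomer length in bp.
#' @param repeat_divergence per-copy substitution rate of repeat copies.
#' @param h_snv per-base SNV heterozygosity (haplotype B vs A).
#' @param h_indel per-base small-indel heterozygosity.
#' @param indel_max largest small-indel length in bp.
#' @param sv_spec optional data.frame (type in INS/DEL, contig, position,
#'   length) of structural variants applied to haplotype B; overlapping
#'   SVs are an error.
#' @param seed integer seed.
#' @return named list of parameters.
#' @export
simParams <- function(genome_length = 5e5, gc = 0.39, repeat_fraction = 0.1,
                      repeat_unit_len = 500L, repeat_divergence = 0.02,
                      h_snv = 0.015, h_indel = 0.001, indel_max = 10L,
                      sv_spec = NULL, seed = 1L) {
  stopIfNot(all(genome_length >= 1e4), "contig lengths must be >= 10 kb")
  rates <- c(gc, repeat_fraction, repeat_divergence, h_snv, h_indel)
  stopIfNot(all(rates >= 0 & rates <= 1), "all rates must be in [0, 1]")
  list(genome_length = genome_length, gc = gc,
       repeat_fraction = repeat_fraction,
       repeat_unit_len = as.integer(repeat_unit_len),
       repeat_divergence = repeat_divergence, h_snv = h_snv,
       h_indel = h_indel, indel_max = as.integer(indel_max),
       sv_spec = sv_spec, seed = as.integer(seed))
}

#' @describeIn simParams long-read profile: lognormal lengths truncated to
#'   \[min_length, max_length\] (mean ~12.5 kb, max ~150 kb, echoing a
#'   filtered nanopore read set), aggregate error drawn per read from
#'   `error_range` and split into substitutions/insertions/deletions by
#'   `mix`. Qualities are a constant Q9: downstream modules ignore base
#'   quality.
#' @param mean_length mean read length before truncation.
#' @param sdlog lognormal sigma.
#' @param min_length,max_length truncation bounds.
#' @param error_range per-read error-rate range (c(0.10, 0.15) is
#'   nanopore-like; c(0, 0) gives error-free reads).
#' @param mix substitution/insertion/deletion composition of errors.
#' @param qual_char constant Phred+33 quality character.
#' @export
longReadProfile <- function(mean_length = 12500, sdlog = 0.55,
                            min_length = 1000L, max_length = 150000L,
                            error_range = c(0.10, 0.15),
                            mix = c(sub = 0.4, ins = 0.3, del = 0.3),
                            qual_char = "*") {
  list(kind = "long", mean_length = mean_length, sdlog = sdlog,
       min_length = as.integer(min_length),
       max_length = as.integer(max_length), error_range = error_range,
       mix = mix / sum(mix), qual_char = qual_char)
}

#' @describeIn simParams short-read profile: fixed-length paired reads
#'   with a Normal insert (mates on opposite strands at the sampled
#'   insert) and substitution-only errors (~0.3%, Illumina-like).
#'   Qualities are a constant Q37.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size distribution.
#' @param error_rate substitution rate.
#' @export
shortReadProfile <- function(read_length = 150L, insert_mean = 400,
                             insert_sd = 40, error_rate = 0.003,
                             qual_char = "F") {
  list(kind = "short", read_length = as.integer(read_length),
       insert_mean = insert_mean, insert_sd = insert_sd,
       error_rate = error_rate, qual_char = qual_char)
}

#' Synthetic diploid genome with ground truth
#'
#' @slot hapA,hapB the two haplotype [Assembly-class] objects.
#' @slot truth list of truth tables: `snv`, `indel`, `sv` (haplotype-A
#'   coordinates, 0-based), `repeats`.
#' @slot params the [simParams()] used.
#' @export
setClass("DiploidGenome",
         representation(hapA = "Assembly", hapB = "Assembly",
                        truth = "list", params = "list"))

setMethod("show", "DiploidGenome", function(object) {
  cat(sprintf(paste0(
    "DiploidGenome: %d contig(s), haploid %s bp\n",
    "  truth: %d SNV, %d small indel, %d SV\n"),
    length(object@hapA), format(totalLength(object@hapA), big.mark = ","),
    nrow(object@truth$snv), nrow(object@truth$indel), nrow(object@truth$sv)))
})

#' @describeIn DiploidGenome haplotype A.
#' @param x a `DiploidGenome`.
#' @export
hapA <- function(x) x@hapA

#' @describeIn DiploidGenome haplotype B.
#' @export
hapB <- function(x) x@hapB

#' @describeIn DiploidGenome the truth tables.
#' @export
simTruth <- function(x) x@truth

randomSeqChars <- function(n, gc) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# substitute n_sub random positions of a character vector with a different
# base (positions returned)
substituteBases <- function(ch, pos) {
  bases <- c("A", "C", "G", "T")
  old <- match(ch[pos], bases)
  old[is.na(old)] <- 1L
  shift <- sample.int(3L, length(pos), replace = TRUE)
  ch[pos] <- bases[(old - 1L + shift) %% 4L + 1L]
  ch
}

#' Simulate a diploid genome
#'
#' Haplotype A is random sequence with a planted dispersed repeat family;
#' haplotype B is derived from A by applying the emitted truth set exactly:
#' SNVs at rate `h_snv`, small indels at `h_indel`, and the structural
#' variants of `sv_spec`. Identical parameters and seed give identical
#' genomes.
#'
#' @param params a [simParams()] list.
#' @return a [DiploidGenome-class].
#' @export
simulateDiploid <- function(params = simParams()) {
  withSeed(params$seed, {
    n_contig <- length(params$genome_length)
    ids <- sprintf("chr%02d", seq_len(n_contig))
    hapA_chr <- character(n_contig)
    rep_rows <- list()
    for (ci in seq_len(n_contig)) {
      L <- as.integer(params$genome_length[ci])
      ch <- randomSeqChars(L, params$gc)
      u <- params$repeat_unit_len
      n_copies <- floor(params$repeat_fraction * L / u)
      if (n_copies > 0) {
        unit <- randomSeqChars(u, params$gc)
        slots <- floor(L / u)
        at <- (sort(sample.int(slots, n_copies)) - 1L) * u  # non-overlapping
        for (p in at) {
          copy <- unit
          nmut <- rbinom(1L, u, params$repeat_divergence)
          if (nmut > 0)
            copy <- substituteBases(copy, sample.int(u, nmut))
          ch[(p + 1L):(p + u)] <- copy
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            contig = ids[ci], start = p, end = p + u,
            stringsAsFactors = FALSE)
        }
      }
      hapA_chr[ci] <- paste(ch, collapse = "")
    }
    names(hapA_chr) <- ids
    # haplotype B: SNVs, small indels, SVs on hapA coordinates
    snv_rows <- list(); indel_rows <- list(); sv_rows <- list()
    hapB_chr <- hapA_chr
    for (ci in seq_len(n_contig)) {
      ch <- strsplit(hapA_chr[[ci]], "")[[1L]]
      L <- length(ch)
      n_snv <- rbinom(1L, L, params$h_snv)
      spos <- sort(sample.int(L, n_snv))
      ref <- ch[spos]
      if (n_snv > 0L) ch <- substituteBases(ch, spos)
      snv_rows[[ci]] <- data.frame(contig = rep(ids[ci], n_snv),
                                   pos = spos - 1L, ref = ref,
                                   alt = ch[spos], stringsAsFactors = FALSE)
      edits <- data.frame(pos = integer(0), type = character(0),
                          len = integer(0))
      n_ind <- rbinom(1L, L, params$h_indel)
      if (n_ind > 0) {
        ipos <- sort(sample.int(L - params$indel_max, n_ind))
        ilen <- sample.int(params$indel_max, n_ind, replace = TRUE)
        itype <- sample(c("INS", "DEL"), n_ind, replace = TRUE)
        edits <- data.frame(pos = ipos - 1L, type = itype, len = ilen)
        indel_rows[[ci]] <- cbind(contig = ids[ci], edits)
      }
      sv <- params$sv_spec
      if (!is.null(sv)) {
        sv_ci <- sv[sv$contig == ids[ci], , drop = FALSE]
        if (nrow(sv_ci)) {
          o <- order(sv_ci$position)
          ends <- sv_ci$position[o] +
            ifelse(sv_ci$type[o] == "DEL", sv_ci$length[o], 0L)
          if (any(sv_ci$position[o][-1L] < ends[-length(ends)]) ||
              any(ends > L))
            stop("inconsistent sv_spec: overlapping or out-of-bounds SVs")
          edits <- rbind(edits, data.frame(pos = sv_ci$position,
                                           type = sv_ci$type,
                                           len = sv_ci$length))
          sv_rows[[length(sv_rows) + 1L]] <- sv_ci
        }
      }
      if (nrow(edits)) {
        # apply right-to-left so earlier coordinates stay valid
        edits <- edits[order(-edits$pos), , drop = FALSE]
        for (e in seq_len(nrow(edits))) {
          p <- edits$pos[e]; l <- edits$len[e]
          if (edits$type[e] == "DEL") {
            ch <- ch[-((p + 1L):min(p + l, length(ch)))]
          } else {
            ins <- randomSeqChars(l, params$gc)
            ch <- append(ch, ins, after = p)
          }
        }
      }
      hapB_chr[[ci]] <- paste(ch, collapse = "")
    }
    truth <- list(
      snv = do.call(rbind, snv_rows),
      indel = if (length(indel_rows)) do.call(rbind, indel_rows)
              else data.frame(contig = character(0), pos = integer(0),
                              type = character(0), len = integer(0)),
      sv = if (length(sv_rows)) do.call(rbind, sv_rows)
           else data.frame(type = character(0), contig = character(0),
                           position = integer(0), length = integer(0)),
      repeats = if (length(rep_rows)) do.call(rbind, rep_rows)
                else data.frame(contig = character(0), start = integer(0),
                                end = integer(0)))
    new("DiploidGenome",
        hapA = Assembly("hapA", hapA_chr),
        hapB = Assembly("hapB", hapB_chr),
        truth = truth, params = params)
  })
}

# draw one read's worth of errors and apply them; returns the mutated string
applyReadErrors <- function(s, e_rate, mix) {
  L <- nchar(s)
  n_err <- rbinom(1L, L, e_rate)
  if (n_err == 0L) return(s)
  ch <- strsplit(s, "")[[1L]]
  kinds <- sample(c("sub", "ins", "del"), n_err, replace = TRUE, prob = mix)
  pos <- sample.int(L, n_err)
  ps <- pos[kinds == "sub"]
  if (length(ps)) ch <- substituteBases(ch, ps)
  pd <- pos[kinds == "del"]
  if (length(pd)) ch[pd] <- ""
  pi <- pos[kinds == "ins"]
  if (length(pi)) ch[pi] <- paste0(ch[pi], randomSeqChars(length(pi), 0.5))
  paste(ch, collapse = "")
}

#' Simulate long reads from a diploid genome
#'
#' Reads are drawn from the two haplotypes with equal probability, from
#' contigs in proportion to length, on a uniform strand, with lognormal
#' lengths and the profile's per-read error rate. The last read is
#' trimmed so total bases hit `coverage` times the haploid length
#' exactly. The true placement of every read is recorded.
#'
#' @param genome a [DiploidGenome-class].
#' @param coverage target fold coverage of the haploid genome.
#' @param profile a [longReadProfile()].
#' @param seed integer seed.
#' @param haplotypes haplotypes reads may come from (default both, equal
#'   probability); `"B"` draws from the variant haplotype only, useful
#'   when the other haplotype plays the reference.
#' @return list: `reads` (named `DNAStringSet` with constant qualities in
#'   `mcols`) and `truth` (data.frame read, haplotype, contig, start, end,
#'   strand, error_rate).
#' @export
simulateLongReads <- function(genome, coverage, profile = longReadProfile(),
                              seed = 1L, haplotypes = c("A", "B")) {
  stopIfNot(coverage > 0, "coverage must be positive")
  stopIfNot(all(haplotypes %in% c("A", "B")), "haplotypes must be A and/or B")
  withSeed(seed, {
    hapoptions <- list(A = hapA(genome), B = hapB(genome))
    target <- coverage * totalLength(hapA(genome))
    meanlog <- log(profile$mean_length) - profile$sdlog^2 / 2
    reads <- character(0); truth <- list()
    total <- 0
    i <- 0L
    while (total < target) {
      i <- i + 1L
      hap <- if (length(haplotypes) == 1L) haplotypes
             else sample(haplotypes, 1L)
      asm <- hapoptions[[hap]]
      lens <- contigLengths(asm)
      ci <- sample.int(length(lens), 1L, prob = lens)
      clen <- lens[[ci]]
      rl <- round(rlnorm(1L, meanlog, profile$sdlog))
      rl <- min(max(rl, profile$min_length), profile$max_length, clen)
      if (total + rl > target) rl <- max(as.integer(target - total), 50L)
      rl <- min(rl, clen)
      start <- sample.int(clen - rl + 1L, 1L) - 1L
      s <- substr(as.character(contigs(asm)[[ci]]), start + 1L, start + rl)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") s <- revcompChr(s)
      e <- runif(1L, profile$error_range[1L], profile$error_range[2L])
      if (e > 0) s <- applyReadErrors(s, e, profile$mix)
      reads[[sprintf("lr%06d", i)]] <- s
      truth[[i]] <- data.frame(
        read = sprintf("lr%06d", i), haplotype = hap,
        contig = contigNames(asm)[ci], start = start, end = start + rl,
        strand = strand, error_rate = e, stringsAsFactors = FALSE)
      total <- total + rl
    }
    out <- DNAStringSet(reads)
    mcols(out)$qualities <- BStringSet(vapply(
      width(out), function(w) strrep(profile$qual_char, w), character(1)))
    list(reads = out, truth = do.call(rbind, truth))
  })
}

#' Simulate paired short reads from a diploid genome
#'
#' Mates sit on opposite strands at a Normal insert; coverage accounting
#' is by pairs, so total bases land within one pair of the target.
#'
#' @param genome a [DiploidGenome-class].
#' @param coverage target fold coverage of the haploid genome.
#' @param profile a [shortReadProfile()].
#' @param seed integer seed.
#' @return list as in [simulateLongReads()]; mate ids carry `/1`/`/2`
#'   suffixes and mates are adjacent.
#' @export
simulateShortReads <- function(genome, coverage, profile = shortReadProfile(),
                               seed = 1L) {
  stopIfNot(coverage > 0, "coverage must be positive")
  withSeed(seed, {
    hapoptions <- list(A = hapA(genome), B = hapB(genome))
    rl <- profile$read_length
    n_pairs <- ceiling(coverage * totalLength(hapA(genome)) / (2 * rl))
    reads <- character(2L * n_pairs)
    nms <- character(2L * n_pairs)
    truth <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      hap <- sample(c("A", "B"), 1L)
      asm <- hapoptions[[hap]]
      lens <- contigLengths(asm)
      ci <- sample.int(length(lens), 1L, prob = lens)
      clen <- lens[[ci]]
      ins <- round(rnorm(1L, profile$insert_mean, profile$insert_sd))
      ins <- min(max(ins, 2L * rl), clen)
      start <- sample.int(clen - ins + 1L, 1L) - 1L
      frag <- substr(as.character(contigs(asm)[[ci]]), start + 1L,
                     start + ins)
      r1 <- substr(frag, 1L, rl)
      r2 <- revcompChr(substr(frag, ins - rl + 1L, ins))
      if (profile$error_rate > 0) {
        r1 <- applyReadErrors(r1, profile$error_rate, c(1, 0, 0))
        r2 <- applyReadErrors(r2, profile$error_rate, c(1, 0, 0))
      }
      reads[2L * i - 1L] <- r1
      reads[2L * i] <- r2
      nms[2L * i - 1L] <- sprintf("sr%06d/1", i)
      nms[2L * i] <- sprintf("sr%06d/2", i)
      truth[[i]] <- data.frame(
        read = sprintf("sr%06d", i), haplotype = hap,
        contig = contigNames(asm)[ci], start = start, end = start + ins,
        strand = "+", error_rate = profile$error_rate,
        stringsAsFactors = FALSE)
    }
    out <- DNAStringSet(setNames(reads, nms))
    mcols(out)$qualities <- BStringSet(vapply(
      width(out), function(w) strrep(profile$qual_char, w), character(1)))
    list(reads = out, truth = do.call(rbind, truth))
  })
}

#' Plant assembly defects with a truth manifest
#'
#' Creates the defects assembly-assessment metrics are designed to expose:
#' `haplotig_duplications` appends a diverged copy of a contig region as a
#' new contig (an unpurged haplotig); `misjoins` reciprocally swap the
#' tails of two contigs at random internal breakpoints (incorrectly linked
#' contigs, which split-read mapping of true reads exposes as
#' translocations); `indel_errors` plant small consensus indels.
#'
#' @param assembly the [Assembly-class] to corrupt.
#' @param spec list with any of `haplotig_duplications`, `haplotig_identity`
#'   (default 0.98), `haplotig_region_frac` (default 1.0), `misjoins`,
#'   `indel_errors`, `indel_max`.
#' @param seed integer seed.
#' @return list: `assembly` (corrupted) and `manifest` (list of truth
#'   data.frames `haplotigs`, `misjoins`, `indels`).
#' @export
corruptAssembly <- function(assembly, spec = list(), seed = 1L) {
  spec <- utils::modifyList(list(haplotig_duplications = 0L,
                                 haplotig_identity = 0.98,
                                 haplotig_region_frac = 1.0,
                                 misjoins = 0L, indel_errors = 0L,
                                 indel_max = 10L), spec)
  withSeed(seed, {
    seqs <- as.character(contigs(assembly))
    man <- list(
      haplotigs = data.frame(new_id = character(0), source = character(0),
                             start = integer(0), end = integer(0),
                             identity = numeric(0), stringsAsFactors = FALSE),
      misjoins = data.frame(contig_a = character(0), contig_b = character(0),
                            break_a = integer(0), break_b = integer(0),
                            stringsAsFactors = FALSE),
      indels = data.frame(contig = character(0), pos = integer(0),
                          type = character(0), len = integer(0),
                          stringsAsFactors = FALSE))
    nh <- spec$haplotig_duplications
    if (nh > 0L) {
      stopIfNot(nh <= length(seqs), "more haplotig duplications than contigs")
      src <- sample(names(seqs), nh)
      for (i in seq_len(nh)) {
        s <- seqs[[src[i]]]
        L <- nchar(s)
        rl <- max(1000L, floor(spec$haplotig_region_frac * L))
        rl <- min(rl, L)
        start <- sample.int(L - rl + 1L, 1L) - 1L
        region <- strsplit(substr(s, start + 1L, start + rl), "")[[1L]]
        nmut <- rbinom(1L, rl, 1 - spec$haplotig_identity)
        if (nmut > 0)
          region <- substituteBases(region, sample.int(rl, nmut))
        nid <- paste0(src[i], "_hap")
        seqs[[nid]] <- paste(region, collapse = "")
        man$haplotigs <- rbind(man$haplotigs, data.frame(
          new_id = nid, source = src[i], start = start, end = start + rl,
          identity = spec$haplotig_identity, stringsAsFactors = FALSE))
      }
    }
    nm <- spec$misjoins
    if (nm > 0L) {
      base_ids <- setdiff(names(seqs), man$haplotigs$new_id)
      stopIfNot(length(base_ids) >= 2L * nm,
                "not enough contigs for the requested misjoins")
      picks <- sample(base_ids, 2L * nm)
      for (i in seq_len(nm)) {
        a <- picks[2L * i - 1L]; b <- picks[2L * i]
        la <- nchar(seqs[[a]]); lb <- nchar(seqs[[b]])
        ba <- sample(seq(floor(0.2 * la), floor(0.8 * la)), 1L)
        bb <- sample(seq(floor(0.2 * lb), floor(0.8 * lb)), 1L)
        new_a <- paste0(substr(seqs[[a]], 1L, ba),
                        substr(seqs[[b]], bb + 1L, lb))
        new_b <- paste0(substr(seqs[[b]], 1L, bb),
                        substr(seqs[[a]], ba + 1L, la))
        seqs[[a]] <- new_a
        seqs[[b]] <- new_b
        man$misjoins <- rbind(man$misjoins, data.frame(
          contig_a = a, contig_b = b, break_a = ba, break_b = bb,
          stringsAsFactors = FALSE))
      }
    }
    ni <- spec$indel_errors
    if (ni > 0L) {
      for (i in seq_len(ni)) {
        cn <- sample(names(seqs), 1L)
        ch <- strsplit(seqs[[cn]], "")[[1L]]
        p <- sample.int(length(ch) - spec$indel_max, 1L)
        l <- sample.int(spec$indel_max, 1L)
        type <- sample(c("INS", "DEL"), 1L)
        if (type == "DEL") ch <- ch[-(p:(p + l - 1L))]
        else ch <- append(ch, randomSeqChars(l, 0.5), after = p)
        seqs[[cn]] <- paste(ch, collapse = "")
        man$indels <- rbind(man$indels, data.frame(
          contig = cn, pos = p - 1L, type = type, len = l,
          stringsAsFactors = FALSE))
      }
    }
    list(assembly = Assembly(paste0(assemblyName(assembly), "_corrupt"),
                             seqs),
         manifest = man)
  })
}

#' Write simulation truth tables to plain-text files
#'
#' Variants go to a TSV (`contig, pos, class, ref/type, alt/len`), SVs to
#' a BED-like TSV.
#'
#' @param genome a [DiploidGenome-class].
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
writeSimTruth <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- simTruth(genome)
  vp <- file.path(dir, "variants.tsv")
  snv <- data.frame(contig = tr$snv$contig, pos = tr$snv$pos, class = "SNV",
                    a = tr$snv$ref, b = tr$snv$alt)
  ind <- if (nrow(tr$indel))
    data.frame(contig = tr$indel$contig, pos = tr$indel$pos, class = "INDEL",
               a = tr$indel$type, b = tr$indel$len)
  else NULL
  write.table(rbind(snv, ind), vp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sp <- file.path(dir, "sv.bed")
  sv <- tr$sv
  write.table(data.frame(contig = sv$contig, start = sv$position,
                         end = sv$position + ifelse(sv$type == "DEL",
                                                    sv$length, 1L),
                         type = sv$type, length = sv$length),
              sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vp, sp))
}
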