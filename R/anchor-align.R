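# Internal pairwise aligner: exact-match anchor seeding, gap-penalised
# chaining, and banded gapped closure of inter-anchor gaps. It plays the
# NUCmer/BLASTN roles of an assembly-comparison pipeline: contig-vs-contig
# alignment, marker mapping, whole-assembly similarity coverage, and binned
# reference coverage. It makes no claim to BLAST statistics: thresholds are
# (identity, coverage, length) triples rather than E-values.

#' Aligner parameter set
#'
#' @param seed_k exact-match seed length (>= 11).
#' @param max_occ seeds occurring more often than this in the target are
#'   skipped as repeat-induced noise (logged).
#' @param band half-width of the banded gap-closure alignment; gaps whose
#'   bounding sequences are <= 400 bp are closed with the exact full DP.
#' @param max_gap largest query/target gap the chainer will bridge; larger
#'   gaps split a chain into separate blocks.
#' @param min_block_len minimum alignment columns for a reported block.
#' @param min_identity minimum percent identity for a reported block.
#' @param gap_open,gap_ext chaining gap penalties (anchor-length units).
#' @param lookback chaining DP look-back window (sorted predecessor count).
#' @return a named list of parameters.
#' @export
alignParams <- function(seed_k = 15L, max_occ = 200L, band = 100L,
                        max_gap = 2000L, min_block_len = 100L,
                        min_identity = 75, gap_open = 4, gap_ext = 0.3,
                        lookback = 64L) {
  stopIfNot(seed_k >= 11L, "seed_k must be >= 11")
  list(seed_k = as.integer(seed_k), max_occ = as.integer(max_occ),
       band = as.integer(band), max_gap = as.integer(max_gap),
       min_block_len = as.integer(min_block_len),
       min_identity = min_identity, gap_open = gap_open, gap_ext = gap_ext,
       lookback = as.integer(lookback))
}

# Build a reusable seed index over target sequences.
buildSeedIndex <- function(seqs, params) {
  seqs_chr <- if (is(seqs, "Assembly")) as.character(contigs(seqs))
              else setNames(as.character(seqs), names(seqs))
  stopIfNot(!is.null(names(seqs_chr)), "target sequences must be named")
  ptr <- .anchor_index_cpp(unname(seqs_chr), names(seqs_chr),
                           params$seed_k, params$max_occ)
  info <- .anchor_index_info_cpp(ptr)
  if (info$dropped_seeds > 0)
    asmqcLog(info$dropped_seeds, " over-represented seed(s) skipped (max_occ=",
             params$max_occ, ")")
  list(ptr = ptr, names = names(seqs_chr), lens = nchar(seqs_chr),
       seqs = seqs_chr, params = params)
}

revcompChr <- function(x) as.character(reverseComplement(DNAStringSet(x)))

#' Seed exact-match anchors between two sequences
#'
#' Reports maximal exact matches of at least `seed_k` bases between the
#' query (or its reverse complement, strand "-") and the target. Anchor
#' coordinates are 0-based in the original query/target frames; for "-"
#' anchors the query interval \[qstart, qstart+len) matches the reverse
#' complement of the target interval.
#'
#' @param query,target single sequences (character or `DNAString`).
#' @param seed_k seed length.
#' @param max_occ repeat-seed occurrence cap.
#' @return data.frame (qstart, tstart, len, strand).
#' @export
seedAnchors <- function(query, target, seed_k = 15L, max_occ = 200L) {
  params <- alignParams(seed_k = seed_k, max_occ = max_occ)
  idx <- buildSeedIndex(setNames(as.character(target), "t"), params)
  q <- as.character(query)
  am <- .anchor_query_cpp(idx$ptr, q)
  if (nrow(am) == 0L)
    return(data.frame(qstart = integer(0), tstart = integer(0),
                      len = integer(0), strand = character(0)))
  qlen <- nchar(q)
  qstart <- ifelse(am[, "strand"] == 1L, am[, "qpos"],
                   qlen - am[, "qpos"] - am[, "len"])
  out <- data.frame(qstart = qstart, tstart = am[, "tpos"], len = am[, "len"],
                    strand = ifelse(am[, "strand"] == 1L, "+", "-"))
  out[order(out$strand, out$qstart, out$tstart), , drop = FALSE]
}

# Close gaps between chained anchors. q and t are sequences in the chain's
# own frame (query reverse-complemented for '-' chains); anchors are rows
# (qpos, tpos, len) ascending in qpos. Returns NULL for degenerate chains.
extendChain <- function(q, t, qpos, tpos, len, params, with_cigar = TRUE) {
  o <- order(qpos, tpos)
  qpos <- qpos[o]; tpos <- tpos[o]; len <- len[o]
  nmatch <- 0; nmis <- 0; nins <- 0; ndel <- 0
  cig <- character(0)
  qs <- qpos[1L]; ts <- tpos[1L]
  prev_q <- qpos[1L]; prev_t <- tpos[1L]  # current ends
  first <- TRUE
  for (i in seq_along(qpos)) {
    a_q <- qpos[i]; a_t <- tpos[i]; a_l <- len[i]
    if (!first) {
      qg <- a_q - prev_q
      tg <- a_t - prev_t
      ov <- max(-min(qg, tg), 0L)
      if (ov >= a_l) next
      a_q <- a_q + ov; a_t <- a_t + ov; a_l <- a_l - ov
      qg <- a_q - prev_q; tg <- a_t - prev_t
      if (qg < 0L || tg < 0L) next  # unequal overlap beyond trim; drop anchor
      if (qg > 0L || tg > 0L) {
        qgap <- substr(q, prev_q + 1L, prev_q + qg)
        tgap <- substr(t, prev_t + 1L, prev_t + tg)
        band <- if (max(qg, tg) <= 400L) max(qg, tg, 1L)
                else abs(qg - tg) + params$band
        aln <- .banded_nw_cpp(qgap, tgap, band)
        nmatch <- nmatch + aln$matches; nmis <- nmis + aln$mismatches
        nins <- nins + aln$ins; ndel <- ndel + aln$del
        if (with_cigar && nzchar(aln$cigar)) cig <- c(cig, aln$cigar)
      }
    }
    nmatch <- nmatch + a_l
    if (with_cigar) cig <- c(cig, paste0(a_l, "="))
    prev_q <- a_q + a_l
    prev_t <- a_t + a_l
    first <- FALSE
  }
  cols <- nmatch + nmis + nins + ndel
  if (cols == 0) return(NULL)
  list(qstart = qs, qend = prev_q, tstart = ts, tend = prev_t,
       matches = nmatch, mismatches = nmis, ins = nins, del = ndel,
       aligned_length = cols, identity = 100 * nmatch / cols,
       cigar = if (with_cigar) collapseCigar(paste0(cig, collapse = ""))
               else NA_character_)
}

# merge adjacent equal CIGAR ops ("4=3=" -> "7=")
collapseCigar <- function(cig) {
  ops <- parseCigar(cig)
  keep_op <- character(0); keep_len <- integer(0)
  for (i in seq_along(ops$op)) {
    if (length(keep_op) && keep_op[length(keep_op)] == ops$op[i]) {
      keep_len[length(keep_len)] <- keep_len[length(keep_len)] + ops$len[i]
    } else {
      keep_op <- c(keep_op, ops$op[i])
      keep_len <- c(keep_len, ops$len[i])
    }
  }
  paste0(keep_len, keep_op, collapse = "")
}

emptyBlockFrame <- function() {
  data.frame(query_id = character(0), target_id = character(0),
             qstart = integer(0), qend = integer(0), tstart = integer(0),
             tend = integer(0), strand = character(0), matches = numeric(0),
             mismatches = numeric(0), ins = numeric(0), del = numeric(0),
             aligned_length = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

# All alignment blocks of one query against an index. Coordinates returned
# in the original query frame. Internal workhorse for the exported surface.
blocksForQuery <- function(qname, qseq, idx, params, with_cigar = FALSE,
                           chains_only = FALSE) {
  am <- .anchor_query_cpp(idx$ptr, qseq)
  if (nrow(am) == 0L) return(if (chains_only) list() else emptyBlockFrame())
  qlen <- nchar(qseq)
  qrc <- NULL
  out <- list()
  keys <- unique(paste(am[, "tid"], am[, "strand"]))
  for (key in keys) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1L]]
    tid <- as.integer(parts[1L]); strand <- as.integer(parts[2L])
    sel <- am[, "tid"] == tid & am[, "strand"] == strand
    qp <- am[sel, "qpos"]; tp <- am[sel, "tpos"]; ln <- am[sel, "len"]
    chains <- .chain_anchors_cpp(qp, tp, ln, params$max_gap,
                                 params$gap_open, params$gap_ext,
                                 params$lookback)
    if (strand == -1L && is.null(qrc)) qrc <- revcompChr(qseq)
    qframe <- if (strand == 1L) qseq else qrc
    tseq <- idx$seqs[[tid]]
    for (ch in chains) {
      if (chains_only) {
        out[[length(out) + 1L]] <- list(
          tid = tid, strand = strand, idx = ch,
          qpos = qp[ch], tpos = tp[ch], len = ln[ch])
        next
      }
      blk <- extendChain(qframe, tseq, qp[ch], tp[ch], ln[ch], params,
                         with_cigar = with_cigar)
      if (is.null(blk)) next
      if (blk$aligned_length < params$min_block_len ||
          blk$identity < params$min_identity) next
      qs <- blk$qstart; qe <- blk$qend
      if (strand == -1L) { qs <- qlen - blk$qend; qe <- qlen - blk$qstart }
      row <- data.frame(query_id = qname, target_id = idx$names[tid],
                        qstart = qs, qend = qe, tstart = blk$tstart,
                        tend = blk$tend,
                        strand = if (strand == 1L) "+" else "-",
                        matches = blk$matches, mismatches = blk$mismatches,
                        ins = blk$ins, del = blk$del,
                        aligned_length = blk$aligned_length,
                        identity = blk$identity, stringsAsFactors = FALSE)
      if (with_cigar) row$cigar <- blk$cigar
      out[[length(out) + 1L]] <- row
    }
  }
  if (chains_only) return(out)
  if (length(out) == 0L) return(emptyBlockFrame())
  res <- do.call(rbind, out)
  res[order(res$target_id, res$tstart, res$qstart), , drop = FALSE]
}

#' Align two sequences into gapped blocks
#'
#' Seeds exact-match anchors, chains co-linear anchors (same strand,
#' consistent diagonal within the gap budget) by the highest-scoring chain,
#' closes inter-anchor gaps by banded global alignment, and reports blocks
#' passing the length and identity filters. Identity is matching columns /
#' alignment columns x 100.
#'
#' @param query,target single sequences (character or `DNAString`).
#' @param params an [alignParams()] list.
#' @return data.frame of blocks: query/target intervals (0-based half-open,
#'   original frames), strand, operation counts, `aligned_length` (columns)
#'   and `identity`.
#' @export
chainAndExtend <- function(query, target, params = alignParams()) {
  idx <- buildSeedIndex(setNames(as.character(target), "target"), params)
  blocksForQuery("query", as.character(query), idx, params)
}

#' Align all contigs of one assembly to another
#'
#' Every contig pair sharing seeds is considered; blocks are filtered at
#' `min_identity`. Swapping the arguments gives the symmetric comparison.
#'
#' @param query_assembly,target_assembly [Assembly-class] objects.
#' @param min_identity minimum percent identity (75 by default, the usual
#'   whole-genome-similarity floor).
#' @param params an [alignParams()] list; its `min_identity` is overridden
#'   by the argument.
#' @return data.frame of blocks as in [chainAndExtend()], with `query_id`
#'   and `target_id` naming contigs.
#' @export
alignAssemblies <- function(query_assembly, target_assembly,
                            min_identity = 75, params = alignParams()) {
  stopIfNot(length(query_assembly) > 0L && length(target_assembly) > 0L,
            "both assemblies must be non-empty")
  params$min_identity <- min_identity
  idx <- buildSeedIndex(target_assembly, params)
  qseqs <- as.character(contigs(query_assembly))
  res <- lapply(names(qseqs), function(qn)
    blocksForQuery(qn, qseqs[[qn]], idx, params))
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) return(emptyBlockFrame())
  rownames(out) <- NULL
  out
}

#' Merged coverage of a reference by alignment blocks
#'
#' Overlapping target intervals are merged so each reference base counts
#' once; the fraction is covered bases over the total reference length.
#'
#' @param blocks block data.frame whose `target_id` names contigs of
#'   `reference`.
#' @param reference the reference [Assembly-class].
#' @return a [CoverageResult-class].
#' @export
referenceCoverage <- function(blocks, reference) {
  lens <- contigLengths(reference)
  ref_total <- totalLength(reference)
  if (nrow(blocks) == 0L)
    return(new("CoverageResult", coveredBases = 0, referenceLength = ref_total,
               fraction = 0,
               intervals = data.frame(contig = character(0), start = integer(0),
                                      end = integer(0))))
  stopIfNot(all(blocks$target_id %in% names(lens)),
            "blocks reference contigs absent from the reference assembly")
  if (any(blocks$tstart < 0 | blocks$tend > lens[blocks$target_id]))
    stop("block interval out of contig bounds")
  iv <- lapply(split(blocks, blocks$target_id), function(b) {
    r <- reduce(IRanges(start = b$tstart + 1L, end = b$tend))
    data.frame(contig = b$target_id[1L], start = start(r) - 1L, end = end(r))
  })
  iv <- do.call(rbind, iv)
  rownames(iv) <- NULL
  covered <- sum(as.numeric(iv$end - iv$start))
  new("CoverageResult", coveredBases = covered, referenceLength = ref_total,
      fraction = covered / ref_total, intervals = iv)
}

#' @describeIn referenceCoverage covered fraction of a `CoverageResult`.
#' @param x a `CoverageResult`.
#' @export
coverageFraction <- function(x) x@fraction

#' Binned, multi-counted coverage of a reference
#'
#' Per-bin value = total aligned target length overlapping the bin divided
#' by the bin length, WITHOUT overlap merging: a reference base aligned
#' twice counts twice (the usual convention for duplication-revealing
#' coverage tracks, and deliberately different from [referenceCoverage()]).
#' The final partial bin is normalised by its true length.
#'
#' @param blocks block data.frame (targets in `reference`).
#' @param reference the reference [Assembly-class].
#' @param bin_size bin width in bp (1 Mb by default).
#' @return data.frame (contig, bin_start, bin_end, value).
#' @export
binnedCoverage <- function(blocks, reference, bin_size = 1e6) {
  lens <- contigLengths(reference)
  out <- lapply(names(lens), function(cn) {
    L <- lens[[cn]]
    starts <- seq(0L, L - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    acc <- numeric(length(starts))
    b <- blocks[blocks$target_id == cn, , drop = FALSE]
    if (nrow(b)) {
      for (i in seq_len(nrow(b))) {
        lo <- b$tstart[i]; hi <- b$tend[i]
        if (hi < lo) stop("block with tend < tstart")
        j <- which(ends > lo & starts < hi)
        acc[j] <- acc[j] + pmin(ends[j], hi) - pmax(starts[j], lo)
      }
    }
    data.frame(contig = cn, bin_start = starts, bin_end = ends,
               value = acc / (ends - starts), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map marker sequences onto an assembly
#'
#' A marker "maps" to a contig when some alignment block attains the
#' identity floor and covers at least `min_cov_frac` of the marker length;
#' one hit is reported per (marker, contig) regardless of how many times
#' the marker aligns there. E-value-style thresholds of database searches
#' are deliberately replaced by this (identity, coverage, length) triple:
#' E-values depend on database size and this aligner is not a database
#' search tool.
#'
#' @param markers named `DNAStringSet` or character vector of nucleotide
#'   marker sequences (conserved genes or any markers).
#' @param assembly the [Assembly-class] to map onto.
#' @param min_identity minimum percent identity (default 80).
#' @param min_cov_frac minimum fraction of the marker covered by one block
#'   (default 0.5).
#' @param params an [alignParams()] list (default `min_block_len` 60 bp).
#' @return data.frame (marker_id, contig_id, tstart, tend, identity).
#' @export
mapMarkers <- function(markers, assembly, min_identity = 80,
                       min_cov_frac = 0.5,
                       params = alignParams(min_block_len = 60L)) {
  params$min_identity <- min_identity
  idx <- buildSeedIndex(assembly, params)
  mseqs <- setNames(as.character(markers), names(markers))
  stopIfNot(!is.null(names(mseqs)), "markers must be named")
  hits <- lapply(names(mseqs), function(mn) {
    b <- blocksForQuery(mn, mseqs[[mn]], idx, params)
    if (nrow(b) == 0L) return(NULL)
    mlen <- nchar(mseqs[[mn]])
    b <- b[(b$qend - b$qstart) >= min_cov_frac * mlen, , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    best <- do.call(rbind, lapply(split(b, b$target_id), function(bb)
      bb[which.max(bb$qend - bb$qstart), , drop = FALSE]))
    data.frame(marker_id = mn, contig_id = best$target_id,
               tstart = best$tstart, tend = best$tend,
               identity = best$identity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(marker_id = character(0), contig_id = character(0),
                      tstart = integer(0), tend = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
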