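# A read-to-assembly bridge over the internal anchor aligner. It exists so
# the evaluation modules are testable end to end without an external
# mapper; SAM from any mapper remains the primary contract. Reads are
# anchored, chained per (contig, strand), the best chain becomes the
# primary alignment and strong chains on disjoint read regions become
# supplementary alignments (split reads), with inter-anchor gaps and read
# ends closed by banded alignment so every aligned base carries explicit
# =/X/I/D operations.

#' Map reads to an assembly with the internal anchor aligner
#'
#' @param reads named `DNAStringSet` or character vector of reads.
#' @param assembly the target [Assembly-class].
#' @param params an [alignParams()] list.
#' @param min_chain_score_frac supplementary chains must score at least
#'   this fraction of the read's best chain.
#' @param max_read_overlap supplementary chains may overlap already-kept
#'   read regions by at most this fraction of their span.
#' @param max_segments at most this many alignment segments per read.
#' @return alignment data.frame in [readSam()] layout (with `cigar` over
#'   =/X/I/D and soft clips); attribute `unmapped` counts reads without an
#'   alignment. Write with [writeSam()] for external tools.
#' @export
mapReads <- function(reads, assembly, params = alignParams(),
                     min_chain_score_frac = 0.4, max_read_overlap = 0.5,
                     max_segments = 4L) {
  seqs <- as.character(reads)
  stopIfNot(!is.null(names(seqs)), "reads must be named")
  idx <- buildSeedIndex(assembly, params)
  unmapped <- 0L
  rows <- list()
  for (rn in names(seqs)) {
    recs <- mapOneRead(rn, seqs[[rn]], idx, params, min_chain_score_frac,
                       max_read_overlap, max_segments)
    if (is.null(recs)) unmapped <- unmapped + 1L
    else rows[[length(rows) + 1L]] <- recs
  }
  out <- if (length(rows)) do.call(rbind, rows) else emptyAlignmentFrame()
  rownames(out) <- NULL
  if (unmapped > 0L) asmqcLog(unmapped, " read(s) unmapped")
  attr(out, "unmapped") <- unmapped
  out
}

mapOneRead <- function(rn, seq, idx, params, min_frac, max_ov, max_segments) {
  qlen <- nchar(seq)
  chains <- blocksForQuery(rn, seq, idx, params, chains_only = TRUE)
  if (length(chains) == 0L) return(NULL)
  score <- vapply(chains, function(ch) sum(ch$len), numeric(1))
  fs <- vapply(chains, function(ch) min(ch$qpos), numeric(1))
  fe <- vapply(chains, function(ch) max(ch$qpos + ch$len), numeric(1))
  strand <- vapply(chains, function(ch) ch$strand, numeric(1))
  rf_start <- ifelse(strand == 1, fs, qlen - fe)
  rf_end <- ifelse(strand == 1, fe, qlen - fs)
  ord <- order(-score, rf_start)
  keep <- integer(0)
  cover <- logical(qlen)
  for (i in ord) {
    if (length(keep) >= max_segments) break
    if (score[i] < min_frac * score[ord[1L]]) break
    span <- (rf_start[i] + 1L):rf_end[i]
    if (sum(cover[span]) > max_ov * length(span)) next
    keep <- c(keep, i)
    cover[span] <- TRUE
  }
  primary <- keep[1L]
  keep <- keep[order(rf_start[keep])]
  # read-frame segment boundaries at midpoints between kept chain spans
  k <- length(keep)
  bounds <- numeric(k + 1L)
  bounds[1L] <- 0L
  bounds[k + 1L] <- qlen
  if (k > 1L)
    for (i in seq_len(k - 1L))
      bounds[i + 1L] <- max(bounds[i], min(qlen, floor(
        (rf_end[keep[i]] + rf_start[keep[i + 1L]]) / 2)))
  qrc <- NULL
  recs <- list()
  for (i in seq_len(k)) {
    ci <- keep[i]
    ch <- chains[[ci]]
    if (strand[ci] == -1 && is.null(qrc)) qrc <- revcompChr(seq)
    qframe <- if (strand[ci] == 1) seq else qrc
    tseq <- idx$seqs[[ch$tid]]
    tlen <- idx$lens[[ch$tid]]
    seg_rf <- c(bounds[i], bounds[i + 1L])
    seg_f <- if (strand[ci] == 1) seg_rf else c(qlen - seg_rf[2L], qlen - seg_rf[1L])
    core <- extendChain(qframe, tseq, ch$qpos, ch$tpos, ch$len, params,
                        with_cigar = TRUE)
    if (is.null(core)) next
    cig <- core$cigar
    nmatch <- core$matches; nmis <- core$mismatches
    nins <- core$ins; ndel <- core$del
    tstart <- core$tstart; tend <- core$tend
    # head extension toward the segment's start
    h <- core$qstart - seg_f[1L]
    avail <- min(h, tstart)
    clip_head <- h - avail
    if (avail > 0L) {
      qh <- substr(qframe, seg_f[1L] + clip_head + 1L, core$qstart)
      th <- substr(tseq, tstart - avail + 1L, tstart)
      aln <- .banded_nw_cpp(qh, th, 24L)
      nmatch <- nmatch + aln$matches; nmis <- nmis + aln$mismatches
      nins <- nins + aln$ins; ndel <- ndel + aln$del
      cig <- paste0(aln$cigar, cig)
      tstart <- tstart - avail
    }
    # tail extension toward the segment's end
    tl <- seg_f[2L] - core$qend
    avail_t <- min(tl, tlen - tend)
    clip_tail <- tl - avail_t
    if (avail_t > 0L) {
      qt <- substr(qframe, core$qend + 1L, seg_f[2L] - clip_tail)
      tt <- substr(tseq, tend + 1L, tend + avail_t)
      aln <- .banded_nw_cpp(qt, tt, 24L)
      nmatch <- nmatch + aln$matches; nmis <- nmis + aln$mismatches
      nins <- nins + aln$ins; ndel <- ndel + aln$del
      cig <- paste0(cig, aln$cigar)
      tend <- tend + avail_t
    }
    if (clip_head > 0L) cig <- paste0(clip_head, "S", cig)
    if (clip_tail > 0L) cig <- paste0(cig, clip_tail, "S")
    cig <- collapseCigar(cig)
    # aligned query interval in read frame
    qa_f <- c(seg_f[1L] + clip_head, seg_f[2L] - clip_tail)
    qa_rf <- if (strand[ci] == 1) qa_f else c(qlen - qa_f[2L], qlen - qa_f[1L])
    recs[[length(recs) + 1L]] <- data.frame(
      query_id = rn, flag = NA_integer_, target_id = idx$names[ch$tid],
      target_start = tstart, target_end = tend,
      strand = if (strand[ci] == 1) "+" else "-", query_len = qlen,
      query_start = qa_rf[1L], query_end = qa_rf[2L],
      is_primary = ci == primary, is_supplementary = ci != primary,
      cigar = cig, aligned_bases = nmatch + nmis, mismatches = nmis,
      ins_bases = nins, del_bases = ndel,
      clip_bases = clip_head + clip_tail,
      edit_distance = nmis + nins + ndel, stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) return(NULL)
  out <- do.call(rbind, recs)
  out$flag <- ifelse(out$strand == "-", 16L, 0L) +
    ifelse(out$is_supplementary, 2048L, 0L)
  out
}
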