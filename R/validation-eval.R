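# Evaluation of an assembly against held-out validation reads: mapping
# rate, base-level error rate, the theoretical error floor, and clustered
# structural-variant counts from gapped and split alignments.

#' Mapping rate and base-level error rate from alignments
#'
#' Only primary alignments are counted. The error rate is
#' (mismatches + inserted bases + deleted bases) / aligned bases, with
#' clipped bases excluded from the denominator — the semantics behind the
#' familiar "errors per mapped base" report figures. Mismatch counts come
#' from =/X CIGARs, MD tags, or NM minus indel bases; records carrying none
#' of these raise an "insufficient tags" error rather than contributing a
#' silent zero.
#'
#' @param alignments alignment data.frame from [readSam()] or [mapReads()].
#' @param reads_total total validation reads (mapped or not), for the
#'   mapping rate denominator.
#' @return a [MappingStats-class].
#' @examples
#' aln <- data.frame(query_id = c("r1", "r2"), is_primary = TRUE,
#'                   aligned_bases = 50L, mismatches = c(1L, 0L),
#'                   ins_bases = 0L, del_bases = 0L)
#' baseErrorRate(aln, reads_total = 2)
#' @export
baseErrorRate <- function(alignments, reads_total) {
  stopIfNot(is.numeric(reads_total) && reads_total > 0,
            "reads_total must be positive")
  prim <- alignments[alignments$is_primary, , drop = FALSE]
  if (any(is.na(prim$mismatches)))
    stop("insufficient tags: mismatch counts unavailable for ",
         sum(is.na(prim$mismatches)), " primary record(s)")
  mapped <- length(unique(prim$query_id))
  stopIfNot(mapped <= reads_total,
            "more mapped reads than reads_total")
  aligned <- sum(as.numeric(prim$aligned_bases))
  mis <- sum(as.numeric(prim$mismatches))
  ins <- sum(as.numeric(prim$ins_bases))
  del <- sum(as.numeric(prim$del_bases))
  new("MappingStats", readsTotal = as.numeric(reads_total),
      readsMapped = as.numeric(mapped),
      mappingRate = 100 * mapped / reads_total,
      alignedBases = aligned, mismatchBases = mis, insertedBases = ins,
      deletedBases = del,
      errorRate = if (aligned > 0) (mis + ins + del) / aligned else NA_real_)
}

#' @describeIn baseErrorRate the error rate of a `MappingStats`.
#' @param x a `MappingStats`.
#' @export
errorRate <- function(x) x@errorRate

#' @describeIn baseErrorRate the mapping rate (%) of a `MappingStats`.
#' @export
mappingRate <- function(x) x@mappingRate

#' Theoretical minimum base-level error rate
#'
#' For a haploid representation of a diploid genome the floor on the
#' validation-read error rate is the sequencing technology's error rate
#' plus half the heterozygosity: a haploid sequence cannot match both
#' alleles, so about half the reads mismatch at every heterozygous site.
#'
#' @param tech_error technology error rate in \[0, 1\].
#' @param heterozygosity per-base heterozygosity in \[0, 1\].
#' @return an [ErrorBound-class].
#' @examples
#' theoreticalMinError(0.003, 0.015)  # 0.0105
#' @export
theoreticalMinError <- function(tech_error, heterozygosity) {
  stopIfNot(tech_error >= 0 && tech_error <= 1,
            "tech_error must be in [0, 1]")
  stopIfNot(heterozygosity >= 0 && heterozygosity <= 1,
            "heterozygosity must be in [0, 1]")
  new("ErrorBound", techError = tech_error, heterozygosity = heterozygosity,
      minimum = tech_error + heterozygosity / 2)
}

#' @describeIn theoreticalMinError the floor of an `ErrorBound`.
#' @param x an `ErrorBound`.
#' @export
errorFloor <- function(x) x@minimum

# --- structural variants ----------------------------------------------------

#' Detect structural variants from validation-read alignments
#'
#' Candidate signatures are (i) intra-alignment insertion/deletion CIGAR
#' operations of at least `min_size` bases and (ii) split-read adjacencies
#' between a read's primary and supplementary alignments: a reference gap
#' of at least `min_size` between consecutive same-contig segments is a
#' deletion signature, an unaligned read gap an insertion signature, and a
#' contig change a translocation signature. Signatures are clustered
#' greedily per (type, contig) within `cluster_window`; an event is
#' reported when supported by at least `min_support` distinct reads, at
#' the median position and median length of its member signatures. This is
#' a deliberate simplification of full SV-caller models (no breakpoint
#' refinement, genotyping, or inversion/duplication classes).
#'
#' @param alignments alignment data.frame (supplementary records must be
#'   retained in the stream: split reads carry the signal).
#' @param min_size minimum SV size in bp (50, the usual caller convention).
#' @param cluster_window clustering window in bp (1000).
#' @param min_support minimum distinct supporting reads (10).
#' @return data.frame (type, contig, position, length, support), one row
#'   per reported event.
#' @export
detectSV <- function(alignments, min_size = 50L, cluster_window = 1000L,
                     min_support = 10L) {
  sig <- svSignatures(alignments, min_size)
  if (nrow(sig) == 0L) return(emptySvFrame())
  events <- list()
  for (key in unique(paste(sig$type, sig$contig))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1L]]
    s <- sig[sig$type == parts[1L] & sig$contig == parts[2L], , drop = FALSE]
    s <- s[order(s$position), , drop = FALSE]
    cl_start <- s$position[1L]
    cl_idx <- 1L
    cl <- rep(NA_integer_, nrow(s))
    for (i in seq_len(nrow(s))) {
      if (s$position[i] - cl_start > cluster_window) {
        cl_idx <- cl_idx + 1L
        cl_start <- s$position[i]
      }
      cl[i] <- cl_idx
    }
    for (g in split(s, cl)) {
      support <- length(unique(g$read_id))
      if (support < min_support) next
      events[[length(events) + 1L]] <- data.frame(
        type = g$type[1L], contig = g$contig[1L],
        position = median(g$position), length = median(g$length),
        support = support, stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) return(emptySvFrame())
  out <- do.call(rbind, events)
  out[order(out$contig, out$position, out$type), , drop = FALSE]
}

emptySvFrame <- function() {
  data.frame(type = character(0), contig = character(0),
             position = numeric(0), length = numeric(0),
             support = integer(0), stringsAsFactors = FALSE)
}

# Extract raw SV signatures (one row per signature occurrence).
svSignatures <- function(alignments, min_size) {
  aln <- alignments[alignments$is_primary | alignments$is_supplementary, ,
                    drop = FALSE]
  rows <- list()
  # intra-alignment I/D operations
  cand <- which(grepl(sprintf("\\d{%d,}[ID]", nchar(as.character(min_size))),
                      aln$cigar))
  for (i in cand) {
    ops <- parseCigar(aln$cigar[i])
    if (!any(ops$op %in% c("I", "D") & ops$len >= min_size)) next
    tpos <- aln$target_start[i]
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; l <- ops$len[k]
      if (op %in% c("I") && l >= min_size)
        rows[[length(rows) + 1L]] <- data.frame(
          type = "INS", contig = aln$target_id[i], position = tpos,
          length = l, read_id = aln$query_id[i], stringsAsFactors = FALSE)
      if (op %in% c("D", "N") && l >= min_size)
        rows[[length(rows) + 1L]] <- data.frame(
          type = "DEL", contig = aln$target_id[i], position = tpos,
          length = l, read_id = aln$query_id[i], stringsAsFactors = FALSE)
      if (op %in% c("M", "=", "X", "D", "N")) tpos <- tpos + l
    }
  }
  # split-read adjacencies
  multi <- names(which(table(aln$query_id) >= 2L))
  for (rid in multi) {
    segs <- aln[aln$query_id == rid, , drop = FALSE]
    segs <- segs[order(segs$query_start), , drop = FALSE]
    for (i in seq_len(nrow(segs) - 1L)) {
      a <- segs[i, ]; b <- segs[i + 1L, ]
      if (a$target_id != b$target_id) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "TRA", contig = a$target_id,
          position = if (a$strand == "+") a$target_end else a$target_start,
          length = 0, read_id = rid, stringsAsFactors = FALSE)
        next
      }
      if (a$strand != b$strand) next  # inversion class: not called
      tgap <- if (a$strand == "+") b$target_start - a$target_end
              else a$target_start - b$target_end
      qgap <- b$query_start - a$query_end
      jpos <- if (a$strand == "+") a$target_end else b$target_end
      if (tgap >= min_size)
        rows[[length(rows) + 1L]] <- data.frame(
          type = "DEL", contig = a$target_id, position = jpos,
          length = tgap, read_id = rid, stringsAsFactors = FALSE)
      if (qgap >= min_size)
        rows[[length(rows) + 1L]] <- data.frame(
          type = "INS", contig = a$target_id, position = jpos,
          length = qgap, read_id = rid, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(type = character(0), contig = character(0),
                      position = numeric(0), length = numeric(0),
                      read_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summarise structural-variant events by type
#'
#' @param events the [detectSV()] table.
#' @return named list with per-type counts (`INS`, `DEL`, `TRA`) and
#'   `total`.
#' @export
svSummary <- function(events) {
  counts <- vapply(c("INS", "DEL", "TRA"),
                   function(tp) sum(events$type == tp), numeric(1))
  c(as.list(counts), list(total = nrow(events)))
}

#' Write SV events as BED-like TSV
#'
#' Columns: contig, start, end, type, length, support (start/end 0-based
#' half-open around the event position).
#'
#' @param events the [detectSV()] table.
#' @param path output TSV.
#' @export
writeSvEvents <- function(events, path) {
  bed <- data.frame(contig = events$contig,
                    start = as.integer(events$position),
                    end = as.integer(events$position) +
                      pmax(as.integer(events$length), 1L),
                    type = events$type, length = events$length,
                    support = events$support)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
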