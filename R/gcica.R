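# Gene Conservation Informed Contig Alignment (GCICA): haplotig detection
# from shared conserved-marker content plus alignment containment, and the
# purge that removes detected haplotigs. In a heterozygous genome, the two
# haplotypes of a region often assemble into two contigs (the longer
# "primary contig" and the shorter "haplotig"); a haplotig carries largely
# the same genes as its primary and is almost fully alignable to it.

#' Detect putative primary-contig/haplotig pairs
#'
#' Markers are mapped to all contigs; for every unordered contig pair with
#' at least one shared marker, the shared-marker fraction is computed on
#' the SMALLER contig's marker set (the containment clause of the rule is
#' about the smaller contig, so its marker set anchors the fraction too;
#' see `share_on`). A pair is a candidate haplotig pair when strictly more
#' than `marker_share` of those markers also map to the larger contig AND
#' at least `containment` of the smaller contig's bases are covered by
#' merged alignment blocks against the larger (strict > for markers, >=
#' for containment). Duplicate placements of a marker within one contig
#' count once: the rule is about marker presence, not multiplicity.
#'
#' @param assembly the [Assembly-class] to screen.
#' @param markers named marker sequences (see [mapMarkers()]).
#' @param marker_share shared-marker threshold (default 0.70, exceeded
#'   strictly).
#' @param containment containment threshold on the smaller contig (default
#'   0.80, met with >=).
#' @param share_on which contig's marker set anchors the shared fraction:
#'   "smaller" (default) or "larger".
#' @param marker_min_identity,marker_min_cov_frac marker-mapping thresholds
#'   passed to [mapMarkers()].
#' @param params [alignParams()] for the containment alignment (identity
#'   floor 75 by default, as for whole-genome similarity).
#' @return data.frame with one row per evaluated pair: larger/smaller ids
#'   and lengths, marker counts, `shared_marker_fraction`,
#'   `containment_fraction` (NA when the marker rule already failed) and
#'   `verdict` ("candidate" or "rejected").
#' @export
detectPairs <- function(assembly, markers, marker_share = 0.70,
                        containment = 0.80, share_on = c("smaller", "larger"),
                        marker_min_identity = 80, marker_min_cov_frac = 0.5,
                        params = alignParams()) {
  share_on <- match.arg(share_on)
  stopIfNot(length(markers) > 0L, "markers must be non-empty")
  stopIfNot(marker_share > 0 && marker_share <= 1,
            "marker_share must be in (0, 1]")
  stopIfNot(containment > 0 && containment <= 1,
            "containment must be in (0, 1]")
  hits <- mapMarkers(markers, assembly, min_identity = marker_min_identity,
                     min_cov_frac = marker_min_cov_frac)
  lens <- contigLengths(assembly)
  msets <- split(hits$marker_id, hits$contig_id)
  no_markers <- setdiff(names(lens), names(msets))
  if (length(no_markers))
    asmqcLog(length(no_markers), " contig(s) with zero mapped markers ",
             "participate only via containment and are never candidates")
  cn <- names(msets)
  if (length(cn) < 2L) return(emptyPairFrame())
  seqs <- as.character(contigs(assembly))
  rows <- list()
  for (i in seq_len(length(cn) - 1L)) {
    for (j in seq((i + 1L), length(cn))) {
      a <- cn[i]; b <- cn[j]
      shared <- intersect(msets[[a]], msets[[b]])
      if (length(shared) == 0L) next
      # larger first; length ties broken lexicographically
      ord <- order(-lens[c(a, b)], c(a, b))
      larger <- c(a, b)[ord[1L]]; smaller <- c(a, b)[ord[2L]]
      anchor_set <- if (share_on == "smaller") msets[[smaller]]
                    else msets[[larger]]
      shared_frac <- length(shared) / length(unique(anchor_set))
      cont_frac <- NA_real_
      verdict <- "rejected"
      if (shared_frac > marker_share) {
        cont_frac <- containmentFraction(seqs[[smaller]], seqs[[larger]],
                                         params)
        if (cont_frac >= containment) verdict <- "candidate"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        larger_id = larger, smaller_id = smaller,
        larger_len = unname(lens[larger]), smaller_len = unname(lens[smaller]),
        n_markers_smaller = length(unique(msets[[smaller]])),
        n_shared = length(shared), shared_marker_fraction = shared_frac,
        containment_fraction = cont_frac, verdict = verdict,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(emptyPairFrame())
  out <- do.call(rbind, rows)
  out[order(-out$shared_marker_fraction, out$larger_id, out$smaller_id), ,
      drop = FALSE]
}

emptyPairFrame <- function() {
  data.frame(larger_id = character(0), smaller_id = character(0),
             larger_len = numeric(0), smaller_len = numeric(0),
             n_markers_smaller = integer(0), n_shared = integer(0),
             shared_marker_fraction = numeric(0),
             containment_fraction = numeric(0), verdict = character(0),
             stringsAsFactors = FALSE)
}

# Fraction of the smaller sequence covered by merged alignment blocks
# against the larger sequence.
containmentFraction <- function(smaller_seq, larger_seq, params) {
  blocks <- chainAndExtend(smaller_seq, larger_seq, params)
  if (nrow(blocks) == 0L) return(0)
  r <- reduce(IRanges(start = blocks$qstart + 1L, end = blocks$qend))
  sum(width(r)) / nchar(smaller_seq)
}

#' Purge detected haplotigs from an assembly
#'
#' In "report" mode nothing is removed: the pair table is returned for
#' review, preserving the examine-by-eye workflow. In "auto" mode the
#' manual confirmation is automated behind a stricter containment
#' threshold: the smaller contig of every candidate pair with
#' `containment_fraction >= auto_containment` is removed. A contig removed
#' once is never removed again through another pair, and a pair whose
#' larger contig was already removed is skipped (chains are logged).
#' Removal order: descending containment, then descending shared fraction,
#' then lexicographic smaller id.
#'
#' @param assembly the [Assembly-class] the pairs were detected on.
#' @param pairs the [detectPairs()] table.
#' @param mode "auto" or "report".
#' @param auto_containment containment needed for automatic removal
#'   (default 0.95, i.e. near-complete containment).
#' @param genome_size optional haploid genome size for before/after ploidy
#'   bookkeeping.
#' @return list with `assembly` (purged) and `report` (a
#'   [PurgeReport-class]).
#' @export
purgeHaplotigs <- function(assembly, pairs, mode = c("auto", "report"),
                           auto_containment = 0.95, genome_size = NULL) {
  mode <- match.arg(mode)
  stopIfNot(all(c(pairs$larger_id, pairs$smaller_id) %in%
                  contigNames(assembly)),
            "pairs reference contigs absent from the assembly")
  len_before <- totalLength(assembly)
  removed <- character(0)
  if (mode == "auto" && nrow(pairs)) {
    cand <- pairs[pairs$verdict == "candidate" &
                    !is.na(pairs$containment_fraction) &
                    pairs$containment_fraction >= auto_containment, ,
                  drop = FALSE]
    cand <- cand[order(-cand$containment_fraction,
                       -cand$shared_marker_fraction, cand$smaller_id), ,
                 drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      sm <- cand$smaller_id[i]; lg <- cand$larger_id[i]
      if (sm %in% removed) next
      if (lg %in% removed) {
        asmqcLog("pair (", lg, ", ", sm, ") skipped: larger contig already ",
                 "removed through another pair")
        next
      }
      removed <- c(removed, sm)
    }
  }
  kept <- setdiff(contigNames(assembly), removed)
  purged <- if (length(removed)) assembly[kept] else assembly
  len_after <- totalLength(purged)
  pb <- pa <- NA_real_
  if (!is.null(genome_size)) {
    pb <- ploidyRatio(assemblyPloidy(len_before, genome_size))
    pa <- ploidyRatio(assemblyPloidy(len_after, genome_size))
  }
  report <- new("PurgeReport", kept = kept, removed = removed, pairs = pairs,
                lengthBefore = len_before, lengthAfter = len_after,
                ploidyBefore = pb, ploidyAfter = pa)
  list(assembly = purged, report = report)
}

#' @describeIn purgeHaplotigs removed contig ids of a `PurgeReport`.
#' @param x a `PurgeReport`.
#' @export
removedContigs <- function(x) x@removed

#' Median per-contig read depth from alignments
#'
#' A coverage sanity-check helper for users who also run read-depth-based
#' haplotig classifiers: haplotigs typically sit near half the assembly-wide
#' depth. No classification is made here.
#'
#' @param alignments alignment data.frame from [readSam()] or [mapReads()].
#' @param assembly the target [Assembly-class].
#' @return data.frame (contig, length, median_depth, mean_depth).
#' @export
contigDepthStats <- function(alignments, assembly) {
  lens <- contigLengths(assembly)
  prim <- alignments[alignments$is_primary | alignments$is_supplementary, ,
                     drop = FALSE]
  out <- lapply(names(lens), function(cn) {
    b <- prim[prim$target_id == cn, , drop = FALSE]
    L <- lens[[cn]]
    if (nrow(b) == 0L)
      return(data.frame(contig = cn, length = L, median_depth = 0,
                        mean_depth = 0, stringsAsFactors = FALSE))
    cov <- coverage(IRanges(start = b$target_start + 1L, end = b$target_end),
                    width = L)
    data.frame(contig = cn, length = L,
               median_depth = median(as.vector(cov)),
               mean_depth = mean(as.vector(cov)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
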