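# Canonical k-mer histograms and haploid genome-size estimation. The
# estimator is the classic mass-over-peak rule: total k-mer mass above the
# error cutoff divided by the homozygous-coverage peak. Counting is exact
# (hash table, no probabilistic sketches) so results are deterministic.

#' Count canonical k-mers into a multiplicity histogram
#'
#' Each k-mer is counted as the lexicographic minimum of itself and its
#' reverse complement, so both strands collapse to one canonical form.
#' k-mers containing N are skipped; multiplicities above `cap` accumulate
#' in the cap bin. Reads shorter than k contribute nothing (logged).
#'
#' @param reads a `DNAStringSet`, character vector or [Assembly-class].
#' @param k k-mer size in \[1, 31\]; 21 by default (odd sizes avoid
#'   self-complementary k-mers dominating).
#' @param cap multiplicity cap (1000 by default, the usual spectrum cap).
#' @return a [KmerHistogram-class].
#' @examples
#' countKmers(c("ACGT", "AAAA", "TTTT"), k = 4)
#' @export
countKmers <- function(reads, k = 21L, cap = 1000L) {
  k <- as.integer(k)
  cap <- as.integer(cap)
  stopIfNot(k >= 1L && k <= 31L, "k must be in [1, 31]")
  seqs <- if (is(reads, "Assembly")) as.character(contigs(reads))
          else as.character(reads)
  short <- sum(nchar(seqs) < k)
  if (short > 0L)
    asmqcLog(short, " read(s) shorter than k=", k, " contribute no k-mers")
  counts <- .kmer_hist_cpp(seqs, k, cap)
  new("KmerHistogram", k = k, cap = cap, counts = counts)
}

#' Write / read a k-mer histogram as two-column TSV
#'
#' The format is two whitespace-separated columns (multiplicity, count),
#' interoperable with Jellyfish `histo` output.
#'
#' @param hist a [KmerHistogram-class].
#' @param path TSV path.
#' @export
writeKmerHistogram <- function(hist, path) {
  nz <- which(hist@counts > 0)
  write.table(data.frame(multiplicity = nz, count = hist@counts[nz]),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeKmerHistogram
#' @param k k-mer size to record on the restored histogram (NA if unknown).
#' @param cap multiplicity cap; defaults to the largest multiplicity present.
#' @export
readKmerHistogram <- function(path, k = NA, cap = NULL) {
  tab <- read.table(path, header = FALSE, col.names = c("m", "n"))
  stopIfNot(nrow(tab) > 0, "empty histogram file")
  cap <- as.integer(cap %||% max(tab$m))
  counts <- numeric(cap)
  m <- pmin(tab$m, cap)
  for (i in seq_along(m)) counts[m[i]] <- counts[m[i]] + tab$n[i]
  new("KmerHistogram", k = as.integer(if (is.na(k)) 0L else k), cap = cap,
      counts = counts)
}

#' Estimate haploid genome size from a k-mer histogram
#'
#' The error cutoff is the first local minimum scanning up from
#' multiplicity 1 (the valley between the sequencing-error tail and the
#' signal peaks); the homozygous peak is the multiplicity maximising the
#' k-mer mass m * counts\[m\] at or above the cutoff, with a diploid
#' disambiguation step: if the mass peak p has a companion peak near 2p
#' (ratio within \[1.8, 2.2\]) carrying at least 20% of its mass, the
#' spectrum is read as heterozygous-dominated and 2p is taken as the
#' homozygous peak. The estimate is mass-above-cutoff / homozygous peak.
#' Mass in the cap bin is included at cap multiplicity, a known source of
#' underestimation for repeat-rich genomes (documented, not corrected).
#'
#' @param hist a [KmerHistogram-class].
#' @param error_cutoff optional explicit cutoff overriding valley detection.
#' @return a [GenomeSizeEstimate-class].
#' @examples
#' h <- new("KmerHistogram", k = 21L, cap = 30L,
#'          counts = replace(numeric(30), c(10, 20), c(30000, 85000)))
#' genomeSize(estimateGenomeSize(h, error_cutoff = 1))
#' @export
estimateGenomeSize <- function(hist, error_cutoff = NULL) {
  counts <- hist@counts
  cap <- hist@cap
  if (is.null(error_cutoff)) {
    if (counts[1L] <= counts[2L]) {
      error_cutoff <- 1L  # no descending error tail at all
    } else {
      error_cutoff <- NA
      for (m in 2:(cap - 1L)) {
        if (counts[m - 1L] > counts[m] && counts[m] <= counts[m + 1L]) {
          error_cutoff <- m
          break
        }
      }
      if (is.na(error_cutoff))
        stop("indistinct error tail: no local minimum found; ",
             "supply error_cutoff explicitly")
    }
  }
  stopIfNot(error_cutoff >= 1 && error_cutoff <= cap,
            "error_cutoff must be within [1, cap]")
  mult <- seq_len(cap)
  mass <- mult * counts
  usable <- mult >= error_cutoff
  stopIfNot(any(usable & mass > 0), "no k-mer mass above the error cutoff")
  # peak location on a lightly smoothed mass curve (window-5 moving
  # average; centre of tied runs) so sampling noise does not drag the
  # arg-max; the size estimate itself always uses the raw mass.
  p <- massPeak(mass, which(usable & mult < cap))
  hom_peak <- p
  # diploid spectrum check: a het peak at lambda/2 can out-mass the
  # homozygous peak at lambda
  win <- which(usable & mult >= 1.8 * p & mult <= 2.2 * p & mult < cap)
  if (length(win)) {
    p2 <- massPeak(mass, win)
    if (smoothedMass(mass)[p2] >= 0.2 * smoothedMass(mass)[p])
      hom_peak <- p2
  }
  mass_used <- sum(mass[usable])
  new("GenomeSizeEstimate", genomeSize = mass_used / hom_peak,
      homPeak = as.numeric(hom_peak), errorCutoff = as.numeric(error_cutoff),
      massUsed = mass_used)
}

smoothedMass <- function(mass, window = 5L) {
  half <- window %/% 2L
  n <- length(mass)
  padded <- c(rep(0, half), mass, rep(0, half))
  vapply(seq_len(n), function(i) mean(padded[i:(i + 2L * half)]), numeric(1))
}

# multiplicity of the mass maximum within candidate bins: locate the peak
# region on the smoothed curve (ties resolve to the centre of the tied run
# so symmetric spikes stay put), then refine to the raw-mass maximum within
# +/-2 bins so hard spectrum edges do not drag the smoothed arg-max
massPeak <- function(mass, candidates) {
  sm <- smoothedMass(mass)[candidates]
  top <- candidates[sm >= max(sm) - 1e-9]
  p0 <- top[ceiling(length(top) / 2)]
  # refine to the mass-weighted centroid of the local neighbourhood:
  # stable under the depth-clumping noise of real spectra and exact on
  # isolated spikes (including spikes at a hard spectrum edge)
  win <- candidates[abs(candidates - p0) <= 5]
  if (sum(mass[win]) <= 0) return(p0)
  ctr <- round(sum(win * mass[win]) / sum(mass[win]))
  win[which.min(abs(win - ctr))]
}
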