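# Contiguity/composition statistics and the assembly-ploidy metric.

#' Contiguity and composition statistics for an assembly
#'
#' N50 is the contig length at which the descending-length cumulative sum
#' first reaches at least half of the assembled bases (>=, not >); L50 is
#' the number of contigs at that crossing. GC is computed over A/C/G/T
#' bases only, while the N percentage is over all bases.
#'
#' @param assembly an [Assembly-class] (must be non-empty).
#' @return an [AssemblyStats-class].
#' @examples
#' a <- Assembly("toy", c(c1 = strrep("AT", 5), c2 = "ATGCNN"))
#' contigStats(a)
#' @export
contigStats <- function(assembly) {
  stopIfNot(is(assembly, "Assembly"), "assembly must be an Assembly")
  stopIfNot(length(assembly) > 0L, "empty assembly")
  lens <- sort(as.numeric(width(contigs(assembly))), decreasing = TRUE)
  total <- sum(lens)
  cum <- cumsum(lens)
  l50 <- which(cum >= total / 2)[1L]
  freq <- colSums(letterFrequency(contigs(assembly), c("A", "C", "G", "T", "N")))
  acgt <- sum(freq[c("A", "C", "G", "T")])
  new("AssemblyStats",
      totalLength = total, contigCount = length(lens),
      largestContig = lens[1L], n50 = lens[l50], l50 = as.integer(l50),
      gcPercent = if (acgt > 0) 100 * sum(freq[c("C", "G")]) / acgt else NA_real_,
      nPercent = 100 * freq[["N"]] / total)
}

#' @describeIn contigStats the N50 in bp.
#' @param x an `AssemblyStats`.
#' @export
n50 <- function(x) x@n50

#' @describeIn contigStats the L50.
#' @export
l50 <- function(x) x@l50

#' Assembly ploidy
#'
#' The ratio of the assembly length to the estimated haploid genome size:
#' ~1 indicates a collapsed haploid representation, ~2 a fully diploid one.
#' Values between flag retained haplotigs. The genome size is an explicit
#' argument, never substituted silently from a k-mer estimate: choosing it
#' is a judgment call that belongs to the analyst.
#'
#' @param assembly_length assembly length in bp, or an [Assembly-class].
#' @param genome_size estimated haploid genome size in bp (> 0).
#' @return a [PloidyResult-class]; the rounded slot uses the conventional
#'   2-decimal report precision.
#' @examples
#' assemblyPloidy(871577052, 500e6)  # 1.74, a near-diploid assembly
#' assemblyPloidy(594871467, 500e6)  # 1.19
#' @export
assemblyPloidy <- function(assembly_length, genome_size) {
  if (is(assembly_length, "Assembly"))
    assembly_length <- totalLength(assembly_length)
  stopIfNot(is.numeric(assembly_length) && assembly_length > 0,
            "assembly_length must be positive")
  stopIfNot(is.numeric(genome_size) && genome_size > 0,
            "genome_size must be positive")
  ratio <- assembly_length / genome_size
  new("PloidyResult", ratio = ratio, ratioRounded = roundHalfUp(ratio, 2),
      assemblyLength = as.numeric(assembly_length),
      genomeSize = as.numeric(genome_size))
}

#' @describeIn assemblyPloidy the raw ratio of a `PloidyResult`.
#' @param x a `PloidyResult`.
#' @export
ploidyRatio <- function(x) x@ratio

#' @describeIn assemblyPloidy the 2-decimal rounded ratio.
#' @export
ploidyRounded <- function(x) x@ratioRounded
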