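#' @import methods
#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet reverseComplement letterFrequency subseq width
#' @importFrom IRanges IRanges reduce coverage start end
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats median rbinom rlnorm rnorm runif
#' @importFrom utils read.delim write.table
#' @useDynLib asmqc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Assembly: a named collection of contigs
#'
#' The central sequence container of the toolkit: an assembly name plus an
#' ordered [Biostrings::DNAStringSet] of contigs with unique non-empty ids.
#' Sequences are normalised to the {A,C,G,T,N} alphabet on construction.
#'
#' @slot name single character, the assembly's name.
#' @slot seqs a named `DNAStringSet` of contigs.
#' @export
setClass("Assembly", representation(name = "character", seqs = "DNAStringSet"))

setValidity("Assembly", function(object) {
  nm <- names(object@seqs)
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("assembly name must be a single non-empty string")
  if (length(object@seqs) == 0L) return(TRUE)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
    return("every contig must have a non-empty id")
  if (anyDuplicated(nm)) return("contig ids must be unique")
  if (any(width(object@seqs) < 1L)) return("contigs must have length >= 1")
  TRUE
})

#' Construct an Assembly
#'
#' @param name assembly name.
#' @param seqs named character vector or `DNAStringSet` of contig sequences.
#' @return an [Assembly-class] object.
#' @examples
#' a <- Assembly("toy", c(c1 = "ACGTACGT", c2 = "GGGCCC"))
#' totalLength(a)
#' @export
Assembly <- function(name, seqs) {
  if (is.character(seqs)) {
    seqs <- DNAStringSet(normalizeAlphabet(seqs, paste0("assembly '", name, "'")))
  } else if (is(seqs, "DNAStringSet")) {
    chr <- as.character(seqs)
    norm <- normalizeAlphabet(chr, paste0("assembly '", name, "'"))
    if (!identical(unname(chr), unname(norm))) {
      nms <- names(seqs)
      seqs <- DNAStringSet(norm)
      names(seqs) <- nms
    }
  } else stop("seqs must be a character vector or DNAStringSet")
  new("Assembly", name = name, seqs = seqs)
}

#' @describeIn Assembly the assembly's name.
#' @param x an `Assembly`.
#' @export
assemblyName <- function(x) x@name

#' @describeIn Assembly the contigs as a `DNAStringSet`.
#' @export
contigs <- function(x) x@seqs

#' @describeIn Assembly contig ids.
#' @export
contigNames <- function(x) names(x@seqs)

#' @describeIn Assembly contig lengths in bp.
#' @export
contigLengths <- function(x) setNames(width(x@seqs), names(x@seqs))

#' @describeIn Assembly total assembly length in bp.
#' @export
totalLength <- function(x) sum(as.numeric(width(x@seqs)))

setMethod("show", "Assembly", function(object) {
  cat("Assembly '", object@name, "': ", length(object@seqs), " contig(s), ",
      format(totalLength(object), big.mark = ","), " bp\n", sep = "")
})

setMethod("length", "Assembly", function(x) length(x@seqs))

setMethod("[", "Assembly", function(x, i, j, ..., drop = TRUE) {
  new("Assembly", name = x@name, seqs = x@seqs[i])
})

#' Canonical k-mer multiplicity histogram
#'
#' @slot k k-mer size.
#' @slot cap multiplicity cap; higher multiplicities accumulate in the cap bin.
#' @slot counts numeric vector; `counts[m]` = number of distinct canonical
#'   k-mers observed at multiplicity `m`.
#' @export
setClass("KmerHistogram",
         representation(k = "integer", cap = "integer", counts = "numeric"))

setValidity("KmerHistogram", function(object) {
  if (length(object@counts) != object@cap)
    return("counts must have one bin per multiplicity in [1, cap]")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' @describeIn KmerHistogram the k-mer size.
#' @param x a `KmerHistogram`.
#' @export
kmerK <- function(x) x@k

#' @describeIn KmerHistogram counts by multiplicity (named vector).
#' @export
histCounts <- function(x) setNames(x@counts, seq_len(x@cap))

#' @describeIn KmerHistogram total k-mer mass, sum over m of m * counts[m].
#' @export
kmerMass <- function(x) sum(seq_len(x@cap) * x@counts)

setMethod("show", "KmerHistogram", function(object) {
  nz <- which(object@counts > 0)
  cat("KmerHistogram: k=", object@k, ", cap=", object@cap,
      ", distinct k-mers=", format(sum(object@counts), big.mark = ","),
      ", mass=", format(kmerMass(object), big.mark = ","), "\n", sep = "")
  if (length(nz))
    cat("  multiplicity range with signal: [", min(nz), ", ", max(nz), "]\n",
        sep = "")
})

#' Haploid genome-size estimate from a k-mer histogram
#'
#' @slot genomeSize estimated haploid genome size in bp.
#' @slot homPeak multiplicity of the homozygous-coverage peak.
#' @slot errorCutoff multiplicity below which k-mers are treated as
#'   sequencing errors.
#' @slot massUsed total k-mer mass at multiplicities >= errorCutoff.
#' @export
setClass("GenomeSizeEstimate",
         representation(genomeSize = "numeric", homPeak = "numeric",
                        errorCutoff = "numeric", massUsed = "numeric"))

#' @describeIn GenomeSizeEstimate the estimated haploid size in bp.
#' @param x a `GenomeSizeEstimate`.
#' @export
genomeSize <- function(x) x@genomeSize

setMethod("show", "GenomeSizeEstimate", function(object) {
  cat(sprintf(
    "GenomeSizeEstimate: %.2f Mb (hom peak %g, error cutoff %g, mass %s)\n",
    object@genomeSize / 1e6, object@homPeak, object@errorCutoff,
    format(object@massUsed, big.mark = ",")))
})

#' Read-set summary statistics
#'
#' Counts, totals, length range and coverage for a read set, mirroring the
#' summary lines of sequencing reports ("x Gb of data (y-fold coverage),
#' average read length z kb").
#'
#' @slot readCount number of reads.
#' @slot totalBases total bases.
#' @slot meanLength mean read length (totalBases / readCount).
#' @slot minLength,maxLength read-length range (NA when unknown).
#' @slot genomeSize genome size used for coverage (NA when not supplied).
#' @slot coverage raw coverage fold (totalBases / genomeSize).
#' @slot coverageFold coverage rounded half-up to an integer fold.
#' @export
setClass("ReadSetSummary",
         representation(readCount = "numeric", totalBases = "numeric",
                        meanLength = "numeric", minLength = "numeric",
                        maxLength = "numeric", genomeSize = "numeric",
                        coverage = "numeric", coverageFold = "numeric"))

setMethod("show", "ReadSetSummary", function(object) {
  cat(sprintf("ReadSetSummary: %s reads, %s bp (mean %.1f bp)\n",
              format(object@readCount, big.mark = ","),
              format(object@totalBases, big.mark = ","), object@meanLength))
  if (!is.na(object@genomeSize))
    cat(sprintf("  coverage: %.2fx (%gx rounded; genome %s bp)\n",
                object@coverage, object@coverageFold,
                format(object@genomeSize, big.mark = ",")))
})

#' Contiguity and composition statistics of an assembly
#'
#' @slot totalLength,contigCount,largestContig,n50,l50 contiguity metrics.
#' @slot gcPercent GC percentage over non-N bases.
#' @slot nPercent N percentage over all bases.
#' @export
setClass("AssemblyStats",
         representation(totalLength = "numeric", contigCount = "integer",
                        largestContig = "numeric", n50 = "numeric",
                        l50 = "integer", gcPercent = "numeric",
                        nPercent = "numeric"))

setMethod("show", "AssemblyStats", function(object) {
  cat(sprintf(paste0(
    "AssemblyStats: %s bp in %d contig(s)\n",
    "  largest %s bp | N50 %s bp | L50 %d | GC %.2f%% | N %.2f%%\n"),
    format(object@totalLength, big.mark = ","), object@contigCount,
    format(object@largestContig, big.mark = ","),
    format(object@n50, big.mark = ","), object@l50,
    object@gcPercent, object@nPercent))
})

#' Assembly ploidy: assembly length over haploid genome size
#'
#' @slot ratio raw ratio.
#' @slot ratioRounded ratio rounded half-up to 2 decimals (report precision).
#' @slot assemblyLength,genomeSize the inputs, in bp.
#' @export
setClass("PloidyResult",
         representation(ratio = "numeric", ratioRounded = "numeric",
                        assemblyLength = "numeric", genomeSize = "numeric"))

setMethod("show", "PloidyResult", function(object) {
  cat(sprintf("PloidyResult: %.2f (%s bp / %s bp)\n", object@ratioRounded,
              format(object@assemblyLength, big.mark = ","),
              format(object@genomeSize, big.mark = ",")))
})

#' Merged alignment coverage of a reference assembly
#'
#' @slot coveredBases reference bases covered by at least one block.
#' @slot referenceLength total reference length.
#' @slot fraction coveredBases / referenceLength.
#' @slot intervals data.frame of merged, disjoint covered intervals
#'   (contig, start, end; 0-based half-open).
#' @export
setClass("CoverageResult",
         representation(coveredBases = "numeric", referenceLength = "numeric",
                        fraction = "numeric", intervals = "data.frame"))

setMethod("show", "CoverageResult", function(object) {
  cat(sprintf("CoverageResult: %s / %s bp covered (%.2f%%)\n",
              format(object@coveredBases, big.mark = ","),
              format(object@referenceLength, big.mark = ","),
              100 * object@fraction))
})

#' Mapping and base-level error statistics from validation-read alignments
#'
#' @slot readsTotal,readsMapped read counts.
#' @slot mappingRate percentage of reads with a primary alignment.
#' @slot alignedBases aligned (non-clipped) read bases.
#' @slot mismatchBases,insertedBases,deletedBases error decomposition.
#' @slot errorRate (mismatch + inserted + deleted) / alignedBases.
#' @export
setClass("MappingStats",
         representation(readsTotal = "numeric", readsMapped = "numeric",
                        mappingRate = "numeric", alignedBases = "numeric",
                        mismatchBases = "numeric", insertedBases = "numeric",
                        deletedBases = "numeric", errorRate = "numeric"))

setMethod("show", "MappingStats", function(object) {
  cat(sprintf(paste0(
    "MappingStats: %s/%s reads mapped (%.2f%%)\n",
    "  error rate %.4f (%s mismatch + %s ins + %s del over %s aligned bases)\n"),
    format(object@readsMapped, big.mark = ","),
    format(object@readsTotal, big.mark = ","), object@mappingRate,
    object@errorRate, format(object@mismatchBases, big.mark = ","),
    format(object@insertedBases, big.mark = ","),
    format(object@deletedBases, big.mark = ","),
    format(object@alignedBases, big.mark = ",")))
})

#' Theoretical minimum base-level error rate
#'
#' For a haploid representation of a diploid genome, validation reads cannot
#' match the assembly at roughly half of the heterozygous sites, so the floor
#' on the base-level error rate is the sequencing technology's error rate
#' plus half the heterozygosity.
#'
#' @slot techError sequencing-technology error rate.
#' @slot heterozygosity per-base heterozygosity.
#' @slot minimum techError + heterozygosity / 2.
#' @export
setClass("ErrorBound",
         representation(techError = "numeric", heterozygosity = "numeric",
                        minimum = "numeric"))

setMethod("show", "ErrorBound", function(object) {
  cat(sprintf("ErrorBound: %.4f (tech %.4f + heterozygosity %.4f / 2)\n",
              object@minimum, object@techError, object@heterozygosity))
})

#' Bookkeeping of a haplotig purge
#'
#' @slot kept,removed contig ids kept and removed.
#' @slot pairs the contig-pair table the purge acted on.
#' @slot lengthBefore,lengthAfter assembly lengths in bp.
#' @slot ploidyBefore,ploidyAfter assembly ploidy when a genome size was
#'   supplied (NA otherwise).
#' @export
setClass("PurgeReport",
         representation(kept = "character", removed = "character",
                        pairs = "data.frame", lengthBefore = "numeric",
                        lengthAfter = "numeric", ploidyBefore = "numeric",
                        ploidyAfter = "numeric"))

setMethod("show", "PurgeReport", function(object) {
  cat(sprintf(paste0(
    "PurgeReport: removed %d of %d contig(s)\n",
    "  length %s -> %s bp"),
    length(object@removed), length(object@kept) + length(object@removed),
    format(object@lengthBefore, big.mark = ","),
    format(object@lengthAfter, big.mark = ",")))
  if (!is.na(object@ploidyBefore))
    cat(sprintf(" | ploidy %.2f -> %.2f", object@ploidyBefore,
                object@ploidyAfter))
  cat("\n")
})

#' Multi-metric assembly comparison table
#'
#' @slot table one row per assembly; first column `assembly`, remaining
#'   columns are metrics.
#' @slot best named list: for each ranked metric, the assembly name(s)
#'   holding the best value (ties jointly).
#' @slot directions named character vector over metric columns with values
#'   "higher", "lower", "target_ploidy" or "info".
#' @slot targetPloidy the ploidy aimed for (1 haploid, 2 diploid).
#' @export
setClass("ComparisonTable",
         representation(table = "data.frame", best = "list",
                        directions = "character", targetPloidy = "numeric"))

setMethod("show", "ComparisonTable", function(object) {
  cat("ComparisonTable:", nrow(object@table), "assemblies x",
      ncol(object@table) - 1L, "metrics\n")
  for (m in names(object@best))
    cat(sprintf("  best %-18s %s\n", paste0(m, ":"),
                paste(object@best[[m]], collapse = ", ")))
})

#' @describeIn ComparisonTable the underlying data.frame.
#' @param x a `ComparisonTable`.
#' @export
reportTable <- function(x) x@table

#' @describeIn ComparisonTable the per-metric best assemblies (named list).
#' @export
bestPerMetric <- function(x) x@best
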