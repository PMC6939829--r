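# Holdout splitting of reads into assembly and validation sets, and read-set
# summaries. The validation set is excluded from assembly and used only to
# evaluate it, so assessment is not biased by reusing the assembly's own data.

#' Randomly split reads into assembly and validation sets
#'
#' Each read (or read pair, in paired mode) is assigned to the validation
#' set by an independent Bernoulli draw with probability
#' `validation_fraction`, under a fixed seed: one streaming pass, expected
#' validation share equal to the fraction, and byte-identical output for
#' identical inputs. Mates are co-assigned: the pair is the unit of the
#' draw, so no pair is ever split across sets.
#'
#' @param reads a named `DNAStringSet` (qualities in `mcols` travel along).
#' @param validation_fraction probability in \[0, 1\] that a read (pair)
#'   goes to the validation set; holdouts of ~10% echo the usual design.
#' @param seed integer seed, recorded in the manifest.
#' @param paired treat consecutive reads as mates; mate ids must agree up to
#'   a trailing `/1`/`/2` suffix.
#' @return list with `assembly` and `validation` read sets and a `manifest`
#'   list (fraction, seed, per-set counts and total bases).
#' @examples
#' reads <- Biostrings::DNAStringSet(setNames(rep("ACGTACGT", 10),
#'                                            paste0("r", 1:10)))
#' sp <- splitReads(reads, 0.3, seed = 1)
#' sp$manifest$validation$read_count
#' @export
splitReads <- function(reads, validation_fraction, seed, paired = FALSE) {
  stopIfNot(validation_fraction >= 0 && validation_fraction <= 1,
            "validation_fraction must be in [0, 1]")
  n <- length(reads)
  if (paired) {
    stopIfNot(n %% 2L == 0L,
              "paired mode requires an even number of reads (adjacent mates)")
    base <- sub("/[12]$", "", names(reads))
    odd <- seq(1L, n, by = 2L)
    mism <- which(base[odd] != base[odd + 1L])
    if (length(mism))
      stop("unmated read in paired mode: ", names(reads)[odd[mism[1L]]])
    units <- length(odd)
  } else units <- n
  take <- withSeed(seed, runif(units) < validation_fraction)
  val_idx <- if (paired) rep(take, each = 2L) else take
  out <- list(assembly = reads[!val_idx], validation = reads[val_idx])
  out$manifest <- list(
    validation_fraction = validation_fraction, seed = as.integer(seed),
    paired = paired,
    input = list(read_count = n, total_bases = sum(as.numeric(width(reads)))),
    assembly = list(read_count = sum(!val_idx),
                    total_bases = sum(as.numeric(width(out$assembly)))),
    validation = list(read_count = sum(val_idx),
                      total_bases = sum(as.numeric(width(out$validation)))))
  out
}

#' Summarise a read set
#'
#' @param reads a `DNAStringSet` (or numeric vector of read lengths).
#' @param genome_size haploid genome size in bp for coverage; NA to skip.
#' @return a [ReadSetSummary-class].
#' @examples
#' summarizeReads(c(100, 300), genome_size = 1000)
#' @export
summarizeReads <- function(reads, genome_size = NA) {
  lens <- if (is.numeric(reads)) reads else as.numeric(width(reads))
  if (length(lens) == 0L)
    return(readSetSummary(0, 0, NA, NA, genome_size))
  readSetSummary(length(lens), sum(lens), min(lens), max(lens), genome_size)
}

#' Build a read-set summary from totals
#'
#' Printed report figures (read counts, total bases) are valid inputs: the
#' derived statistics are mean length, raw coverage and the conventional
#' half-up integer coverage fold ("174x"-style).
#'
#' @param read_count number of reads.
#' @param total_bases total bases.
#' @param min_length,max_length optional length range.
#' @param genome_size haploid genome size in bp; NA to skip coverage.
#' @return a [ReadSetSummary-class].
#' @examples
#' ## 86.98 Gb of long reads over a 500 Mb genome is a 174-fold dataset
#' readSetSummary(7e6, 86.98e9, genome_size = 500e6)
#' @export
readSetSummary <- function(read_count, total_bases, min_length = NA,
                           max_length = NA, genome_size = NA) {
  stopIfNot(is.na(genome_size) || genome_size > 0,
            "genome_size must be positive")
  cov <- if (is.na(genome_size)) NA_real_ else total_bases / genome_size
  new("ReadSetSummary",
      readCount = as.numeric(read_count), totalBases = as.numeric(total_bases),
      meanLength = if (read_count > 0) total_bases / read_count else NA_real_,
      minLength = as.numeric(min_length), maxLength = as.numeric(max_length),
      genomeSize = as.numeric(genome_size), coverage = cov,
      coverageFold = if (is.na(cov)) NA_real_ else roundHalfUp(cov))
}

#' @describeIn readSetSummary raw coverage fold of a summary.
#' @param x a `ReadSetSummary`.
#' @export
coverageFold <- function(x) x@coverageFold

#' @describeIn readSetSummary mean read length of a summary.
#' @export
meanReadLength <- function(x) x@meanLength
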