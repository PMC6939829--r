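# FASTA / FASTQ / SAM readers and writers: the I/O boundary every other
# module consumes. Coordinates are 0-based half-open everywhere internally;
# SAM's 1-based closed coordinates are converted here at the parser boundary.

#' Read a FASTA file of contigs
#'
#' Sequences are uppercased and IUPAC codes outside {A,C,G,T,N} are mapped
#' to N (logged). The id is the header token before the first whitespace.
#'
#' @param path FASTA file (plain or gzip).
#' @param name optional assembly name; defaults to the file name.
#' @return an [Assembly-class].
#' @export
readFasta <- function(path, name = NULL) {
  seqs <- readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L)
    return(Assembly(name %||% basename(path), DNAStringSet()))
  ids <- sub("\\s.*$", "", names(seqs))
  empty <- which(width(seqs) == 0L)
  if (length(empty))
    stop("FASTA record with empty sequence: ", ids[empty[1L]])
  names(seqs) <- ids
  Assembly(name %||% basename(path), seqs)
}

#' Write contigs to FASTA
#'
#' @param x an [Assembly-class] or named `DNAStringSet`.
#' @param path output file; `.gz` suffix writes gzip.
#' @export
writeFasta <- function(x, path) {
  seqs <- if (is(x, "Assembly")) contigs(x) else DNAStringSet(x)
  writeXStringSet(seqs, path, format = "fasta",
                  compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file of reads
#'
#' @param path FASTQ file (plain or gzip), 4-line records, Phred+33.
#' @return a named `DNAStringSet`; per-base qualities are kept in
#'   `mcols(x)$qualities` as a `BStringSet`.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)  # file() transparently decompresses gzip
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) {
    out <- DNAStringSet()
    mcols(out)$qualities <- BStringSet()
    return(out)
  }
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: line count not a multiple of 4")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@")))
    stop("malformed FASTQ: record header lacking '@'")
  ids <- sub("\\s.*$", "", substring(ids, 2L))
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    stop("FASTQ quality/sequence length mismatch in record: ", ids[bad[1L]])
  out <- DNAStringSet(setNames(toupper(seqs), ids))
  mcols(out)$qualities <- BStringSet(quals)
  out
}

#' Write reads to FASTQ
#'
#' @param reads named `DNAStringSet`; qualities are taken from
#'   `mcols(reads)$qualities` when present, else a constant `default_qual`.
#' @param path output file; `.gz` suffix writes gzip.
#' @param default_qual single Phred+33 character used when no qualities are
#'   attached.
#' @export
writeFastq <- function(reads, path, default_qual = "I") {
  quals <- mcols(reads)$qualities
  if (is.null(quals))
    quals <- BStringSet(vapply(width(reads), function(w)
      strrep(default_qual, w), character(1)))
  writeXStringSet(reads, path, format = "fastq", qualities = quals,
                  compress = grepl("\\.gz$", path))
  invisible(path)
}

# --- CIGAR utilities --------------------------------------------------------

parseCigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  list(op = substring(toks, nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

cigarOpSums <- function(ops) {
  s <- function(set) sum(ops$len[ops$op %in% set])
  list(aligned = s(c("M", "=", "X")), x = s("X"), eq = s("="),
       m = s("M"), ins = s("I"), del = s(c("D", "N")),
       clip = s(c("S", "H")), soft = s("S"), hard = s("H"))
}

# Count mismatch letters in an MD tag (deleted reference bases after '^' are
# not mismatches).
mdMismatches <- function(md) {
  md <- gsub("\\^[A-Z]+", "", md)
  nchar(gsub("[0-9]", "", md))
}

# --- SAM --------------------------------------------------------------------

#' Parse read-to-assembly alignments from SAM
#'
#' Plain-text SAM is the contract: any mapper's output can be consumed.
#' Unmapped records are skipped but counted; secondary records are dropped
#' when `primary_only`; supplementary records are retained and flagged (the
#' structural-variant caller needs split reads). Coordinates are converted
#' to 0-based half-open. Per-record mismatch counts are taken from =/X CIGAR
#' operations when present, else the MD tag, else NM minus indel bases; when
#' none is available the count is NA and, with `require_mismatches = TRUE`,
#' an "insufficient tags" error is raised rather than a silent 0.
#'
#' @param path SAM file.
#' @param primary_only drop secondary alignments (default TRUE).
#' @param require_mismatches error when a record's mismatch count cannot be
#'   derived.
#' @return a data.frame with one row per kept record: `query_id`, `flag`,
#'   `target_id`, `target_start`, `target_end`, `strand`, `query_len`,
#'   `query_start`, `query_end` (read frame, 0-based half-open, clips
#'   excluded), `is_primary`, `is_supplementary`, `cigar`, `aligned_bases`,
#'   `mismatches`, `ins_bases`, `del_bases`, `clip_bases`, `edit_distance`.
#'   Attributes `skipped_unmapped` and `dropped_secondary` carry the tallies.
#' @export
readSam <- function(path, primary_only = TRUE, require_mismatches = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "@")]
  skipped <- 0L
  dropped_secondary <- 0L
  rows <- vector("list", length(lines))
  n <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("malformed SAM record: ", substr(ln, 1, 60))
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) > 0L) { skipped <- skipped + 1L; next }
    secondary <- bitwAnd(flag, 256L) > 0L
    if (secondary && primary_only) {
      dropped_secondary <- dropped_secondary + 1L; next
    }
    if (f[6L] == "*")
      stop("mapped SAM record lacking CIGAR: ", f[1L])
    ops <- parseCigar(f[6L])
    sums <- cigarOpSums(ops)
    tags <- if (length(f) > 11L) f[12:length(f)] else character(0)
    nm <- tags[startsWith(tags, "NM:i:")]
    md <- tags[startsWith(tags, "MD:Z:")]
    nm <- if (length(nm)) as.integer(sub("NM:i:", "", nm[1L])) else NA_integer_
    mism <- if (sums$x > 0L || sums$eq > 0L) {
      sums$x
    } else if (length(md)) {
      mdMismatches(sub("MD:Z:", "", md[1L]))
    } else if (!is.na(nm)) {
      max(nm - sums$ins - sums$del, 0L)
    } else NA_integer_
    if (require_mismatches && is.na(mism))
      stop("insufficient tags: record '", f[1L],
           "' has neither NM, MD, nor =/X CIGAR operations")
    qlen <- sums$aligned + sums$ins + sums$clip
    lead <- if (ops$op[1L] %in% c("S", "H")) ops$len[1L] else 0L
    nop <- length(ops$op)
    trail <- if (ops$op[nop] %in% c("S", "H")) ops$len[nop] else 0L
    reverse <- bitwAnd(flag, 16L) > 0L
    qs_rec <- lead
    qe_rec <- qlen - trail
    rows[[n <- n + 1L]] <- data.frame(
      query_id = f[1L], flag = flag, target_id = f[3L],
      target_start = as.integer(f[4L]) - 1L,
      target_end = as.integer(f[4L]) - 1L + sums$aligned + sums$del,
      strand = if (reverse) "-" else "+",
      query_len = qlen,
      query_start = if (reverse) qlen - qe_rec else qs_rec,
      query_end = if (reverse) qlen - qs_rec else qe_rec,
      is_primary = !secondary && bitwAnd(flag, 2048L) == 0L,
      is_supplementary = bitwAnd(flag, 2048L) > 0L,
      cigar = f[6L], aligned_bases = sums$aligned, mismatches = mism,
      ins_bases = sums$ins, del_bases = sums$del, clip_bases = sums$clip,
      edit_distance = if (!is.na(nm)) nm else mism + sums$ins + sums$del,
      stringsAsFactors = FALSE)
  }
  out <- if (n == 0L) emptyAlignmentFrame() else do.call(rbind, rows[seq_len(n)])
  if (skipped > 0L) asmqcLog(skipped, " unmapped record(s) skipped")
  attr(out, "skipped_unmapped") <- skipped
  attr(out, "dropped_secondary") <- dropped_secondary
  out
}

emptyAlignmentFrame <- function() {
  data.frame(query_id = character(0), flag = integer(0),
             target_id = character(0), target_start = integer(0),
             target_end = integer(0), strand = character(0),
             query_len = integer(0), query_start = integer(0),
             query_end = integer(0), is_primary = logical(0),
             is_supplementary = logical(0), cigar = character(0),
             aligned_bases = integer(0), mismatches = integer(0),
             ins_bases = integer(0), del_bases = integer(0),
             clip_bases = integer(0), edit_distance = integer(0),
             stringsAsFactors = FALSE)
}

#' Write alignment records to SAM
#'
#' Emits the same dialect [readSam()] consumes (=/X CIGARs, NM tags), so
#' records produced by [mapReads()] round-trip exactly.
#'
#' @param records alignment data.frame in [readSam()] layout.
#' @param path output SAM path.
#' @param target_lengths named vector of target sequence lengths for the
#'   `@SQ` header (an [Assembly-class] is also accepted).
#' @export
writeSam <- function(records, path, target_lengths) {
  if (is(target_lengths, "Assembly"))
    target_lengths <- contigLengths(target_lengths)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(target_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths)[i],
                       as.integer(target_lengths[i])), con)
  if (nrow(records) == 0L) return(invisible(path))
  flag <- ifelse(records$strand == "-", 16L, 0L) +
    ifelse(records$is_supplementary, 2048L, 0L) +
    ifelse(!records$is_primary & !records$is_supplementary, 256L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tNM:i:%d",
                   records$query_id, flag, records$target_id,
                   records$target_start + 1L, records$cigar,
                   records$mismatches + records$ins_bases + records$del_bases)
  writeLines(lines, con)
  invisible(path)
}
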