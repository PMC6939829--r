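# The comparison report: merge computed and externally supplied metrics
# into one table per assembly, flag the best assembly per measure, and
# rank. Completeness scores (BUSCO), repeat-space indices (LAI) and
# alignment likelihoods (CGAL) come from external tools and enter as
# config values; they are never computed here.

#' Default metric directions
#'
#' "higher" marks higher-is-better metrics (N50, complete conserved genes,
#' LAI, mapping rates, CGAL likelihood), "lower" lower-is-better (error
#' rates, SV totals, duplicated/fragmented gene counts),
#' "target_ploidy" distance-to-target (an assembly ploidy of 1 is
#' preferable for a haploid goal, 2 for a diploid one), and "info"
#' excludes a column from best-marking.
#'
#' @return named character vector usable as `directions` in
#'   [assembleReport()].
#' @export
defaultDirections <- function() {
  c(length = "info", contig_count = "info", n50 = "higher",
    busco_complete = "higher", busco_complete_pct = "higher",
    busco_duplicated = "lower", busco_duplicated_pct = "lower",
    busco_fragmented = "lower", busco_fragmented_pct = "lower",
    lai = "higher", ploidy = "target_ploidy",
    short_mapping_rate = "higher", short_error_rate = "lower",
    long_mapping_rate = "higher", long_error_rate = "lower",
    cgal = "higher", sv_total = "lower")
}

#' Assemble a multi-metric comparison table
#'
#' @param rows data.frame with an `assembly` column and one column per
#'   metric; NA entries are allowed (a metric column with NAs is skipped
#'   for the rows concerned).
#' @param directions named character vector over metric columns with
#'   values "higher", "lower", "target_ploidy" or "info"; defaults from
#'   [defaultDirections()] for known names. A metric column without a
#'   direction is an error.
#' @param target_ploidy ploidy aimed for (1 haploid, 2 diploid).
#' @return a [ComparisonTable-class]; ties share the best marker.
#' @export
assembleReport <- function(rows, directions = NULL, target_ploidy = 1) {
  stopIfNot(is.data.frame(rows) && nrow(rows) >= 1L,
            "rows must be a non-empty data.frame")
  stopIfNot("assembly" %in% names(rows), "rows must have an assembly column")
  stopIfNot(!anyDuplicated(rows$assembly), "duplicate assembly names")
  metric_cols <- setdiff(names(rows), "assembly")
  dirs <- defaultDirections()
  if (!is.null(directions)) dirs[names(directions)] <- directions
  missing_dir <- setdiff(metric_cols, names(dirs))
  if (length(missing_dir))
    stop("no direction specified for column(s): ",
         paste(missing_dir, collapse = ", "))
  dirs <- dirs[metric_cols]
  best <- list()
  for (m in metric_cols) {
    d <- dirs[[m]]
    if (d == "info") next
    v <- rows[[m]]
    if (all(is.na(v))) next
    key <- switch(d,
                  higher = -v,
                  lower = v,
                  target_ploidy = abs(v - target_ploidy),
                  stop("unknown direction '", d, "' for column ", m))
    win <- which(!is.na(key) & key == min(key, na.rm = TRUE))
    best[[m]] <- rows$assembly[win]
  }
  new("ComparisonTable", table = rows, best = best,
      directions = dirs, targetPloidy = target_ploidy)
}

#' Rank assemblies across metrics (Borda count)
#'
#' Each ranked metric contributes its per-assembly rank (1 = best, ties
#' averaged); the Borda score is the sum and the final rank orders the
#' scores (ties share a rank). The scheme is advisory: a defensible
#' overall choice weighs metrics with judgment, which is why the
#' per-metric ranks are returned alongside.
#'
#' @param ct a [ComparisonTable-class] with at least 2 rows.
#' @param scheme ranking scheme; only "borda" is implemented.
#' @return data.frame (assembly, borda_score, rank), best first, with the
#'   per-metric rank matrix in attribute `metric_ranks`.
#' @export
rankAssemblies <- function(ct, scheme = "borda") {
  stopIfNot(identical(scheme, "borda"), "only the borda scheme is available")
  rows <- ct@table
  stopIfNot(nrow(rows) >= 2L, "ranking needs at least 2 assemblies")
  dirs <- ct@directions
  ranked_cols <- names(dirs)[dirs != "info"]
  rk <- sapply(ranked_cols, function(m) {
    v <- rows[[m]]
    if (all(is.na(v))) return(rep(NA_real_, nrow(rows)))
    key <- switch(dirs[[m]],
                  higher = -v,
                  lower = v,
                  target_ploidy = abs(v - ct@targetPloidy))
    rank(key, ties.method = "average", na.last = "keep")
  })
  rownames(rk) <- rows$assembly
  score <- rowSums(rk, na.rm = TRUE)
  out <- data.frame(assembly = rows$assembly, borda_score = score,
                    rank = rank(score, ties.method = "min"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$assembly), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metric_ranks") <- rk
  out
}

#' Write / read a comparison report
#'
#' The JSON form round-trips the full table, directions, best markers and
#' target ploidy; the TSV form is the flat table with a `best_in` column
#' listing the metrics each assembly wins.
#'
#' @param ct a [ComparisonTable-class].
#' @param tsv_path,json_path output paths (either may be NULL).
#' @return invisible `ct`.
#' @export
writeReport <- function(ct, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    tab <- ct@table
    tab$best_in <- vapply(tab$assembly, function(a)
      paste(names(ct@best)[vapply(ct@best, function(w) a %in% w, logical(1))],
            collapse = ","), character(1))
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(table = ct@table, best = ct@best,
           directions = as.list(ct@directions),
           target_ploidy = ct@targetPloidy),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(ct)
}

#' @rdname writeReport
#' @param path JSON path written by `writeReport`.
#' @export
readReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  best <- lapply(x$best, function(b) as.character(unlist(b)))
  new("ComparisonTable", table = as.data.frame(x$table),
      best = best, directions = unlist(x$directions),
      targetPloidy = as.numeric(x$target_ploidy))
}

#' Bundled nine-assembly example metrics
#'
#' Loads the packaged example table of published final-assembly metrics
#' for nine *Eucalyptus pauciflora* draft assemblies (contiguity, gene
#' completeness, ploidy, validation-read mapping and error rates, CGAL
#' likelihood and SV totals), useful as a worked report input.
#'
#' @return data.frame in [assembleReport()] layout.
#' @export
exampleAssemblyMetrics <- function() {
  path <- system.file("extdata", "eucalyptus_assembly_metrics.tsv",
                      package = "asmqc", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
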