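## File readers/writers (CSV cohort tables, tabular-text matrices,
## parcel maps) and survey/demographic summarization.

#' Round half-up
#'
#' Decimal rounding with ties away from zero (the convention of printed
#' survey tables), unlike \code{round()}'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a cohort total from printed counts
#'
#' \code{100 * sum(count) / n_total}, rounded half-up to 2 decimals —
#' the arithmetic of printed survey tables, including bracket unions
#' (pass several counts to union levels).
#'
#' @param count one or more response-level counts.
#' @param n_total cohort denominator.
#' @export
surveyPercent <- function(count, n_total) {
  roundHalfUp(100 * sum(count) / n_total, 2L)
}

#' Summarize ordinal/categorical survey responses
#'
#' Counts and cohort percentages per response level, with missing responses
#' tracked separately and optional level unions (e.g. income brackets below
#' a cutoff). Percentages use the cohort total \code{n_total} as the
#' denominator and are rounded half-up to 2 decimals.
#'
#' @param table cohort data.frame.
#' @param item response column name.
#' @param levels expected levels, in display order; defaults to the sorted
#'   observed levels. A response outside this set is an error.
#' @param unions named list of level vectors to aggregate, e.g.
#'   \code{list(low_income = 1:3)}.
#' @param n_total denominator for percentages (defaults to \code{nrow(table)}).
#' @return list with data.frames \code{levels} (level, count, percentage)
#'   and \code{unions}, plus \code{n_missing} and \code{n_total}.
#' @export
summarizeSurvey <- function(table, item, levels = NULL, unions = list(),
                            n_total = nrow(table)) {
  if (!item %in% names(table)) stop("column not found in table: ", item)
  x <- table[[item]]
  n_missing <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (is.null(levels)) levels <- sort(unique(x))
  unknown <- setdiff(unique(x), levels)
  if (length(unknown) > 0L)
    stop("unknown response level for item '", item, "': ", unknown[1L])
  counts <- vapply(levels, function(l) sum(x == l), numeric(1))
  lev_df <- data.frame(level = levels, count = as.integer(counts),
                       percentage = surveyPercentVec(counts, n_total),
                       stringsAsFactors = FALSE)
  uni_df <- NULL
  if (length(unions) > 0L) {
    uni_df <- do.call(rbind, lapply(names(unions), function(nm) {
      lv <- unions[[nm]]
      bad <- setdiff(lv, levels)
      if (length(bad) > 0L)
        stop("unknown response level in union '", nm, "': ", bad[1L])
      cnt <- sum(counts[match(lv, levels)])
      data.frame(union = nm, count = as.integer(cnt),
                 percentage = surveyPercent(cnt, n_total),
                 stringsAsFactors = FALSE)
    }))
  }
  list(levels = lev_df, unions = uni_df, n_missing = n_missing,
       n_total = n_total)
}

surveyPercentVec <- function(counts, n_total)
  vapply(counts, surveyPercent, numeric(1), n_total = n_total)

#' Write / read a cohort table as CSV
#'
#' RFC-4180-style CSV with a header row.
#'
#' @param table data.frame to write.
#' @param path file path.
#' @export
writeCohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @param required_cols columns that must be present (schema check).
#' @export
readCohort <- function(path, required_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_cols, names(tab))
  if (length(missing_cols) > 0L)
    stop("cohort file ", path, " is missing column: ", missing_cols[1L])
  tab
}

#' Write / read a square matrix as tabular text
#'
#' Tab-separated text with row and column identifiers; values are written
#' with 17 significant digits, so numeric round-trips are exact to printed
#' precision.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @export
writeMatrix <- function(m, path) {
  df <- as.data.frame(m)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname writeMatrix
#' @param check_symmetric error on a non-symmetric matrix (the default:
#'   connectivity/adjacency inputs must be symmetric).
#' @param tol symmetry tolerance.
#' @export
readMatrix <- function(path, check_symmetric = TRUE, tol = 1e-9) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square (", nrow(m), " x ", ncol(m), ")")
  if (check_symmetric && max(abs(m - t(m))) > tol)
    stop("matrix in ", path, " is not symmetric")
  m
}

#' Write / read a parcel-to-network map
#'
#' Three-column tab-separated text: parcel_id, network, hemisphere.
#'
#' @param map a \code{\linkS4class{ParcellationMap}}.
#' @param path file path.
#' @export
writeParcellationMap <- function(map, path) {
  utils::write.table(mapEntries(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeParcellationMap
#' @param required_parcels parcel ids that must be covered; an uncovered
#'   parcel is an error naming it.
#' @export
readParcellationMap <- function(path, required_parcels = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("parcel_id", "network", "hemisphere"), names(e))
  if (length(missing_cols) > 0L)
    stop("map file ", path, " is missing column: ", missing_cols[1L])
  uncovered <- setdiff(required_parcels, e$parcel_id)
  if (length(uncovered) > 0L)
    stop("map file ", path, " is missing parcel: ", uncovered[1L])
  new("ParcellationMap", entries = e)
}
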