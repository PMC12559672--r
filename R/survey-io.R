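#' Construct a survey set
#'
#' A survey set is the package's central container: one row per
#' (period, patch, species) combination observed during a count, plus the
#' ordered list of hydrological periods the records span.
#'
#' @param records data frame with columns `period`, `patch_id`, `subregion`,
#'   `species`, `functional_group`, `count`.
#' @param periods character vector giving the period order. Defaults to
#'   first-appearance order in `records`.
#' @return An object of class `survey_set`: a list with elements `records`
#'   (data frame) and `periods` (character).
#' @export
survey_set <- function(records, periods = NULL) {
  needed <- c("period", "patch_id", "subregion", "species",
              "functional_group", "count")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("survey records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[needed]
  for (col in needed[-6L]) records[[col]] <- as.character(records[[col]])
  records$count <- as.numeric(records$count)
  bad <- which(is.na(records$count) | records$count < 0)
  if (length(bad) > 0L) {
    stop("negative or non-numeric count at row ", bad[1L], call. = FALSE)
  }
  if (is.null(periods)) {
    periods <- unique(records$period)
  } else {
    periods <- as.character(periods)
  }
  if (anyDuplicated(periods)) stop("duplicate period labels", call. = FALSE)
  if (nrow(records) > 0L) {
    unknown <- setdiff(unique(records$period), periods)
    if (length(unknown) > 0L) {
      stop("records contain period(s) not in the period list: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    # collapse duplicate (period, patch, species) keys by summation
    key <- paste(records$period, records$patch_id, records$species, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- tapply(records$count, key, sum)
      first <- records[!duplicated(key), , drop = FALSE]
      first$count <- as.numeric(agg[paste(first$period, first$patch_id,
                                          first$species, sep = "\r")])
      records <- first
    }
    rownames(records) <- NULL
  }
  structure(list(records = records, periods = periods), class = "survey_set")
}

#' @export
print.survey_set <- function(x, ...) {
  cat("survey_set:", nrow(x$records), "records,",
      length(unique(x$records$patch_id)), "patches,",
      length(unique(x$records$species)), "species,",
      length(x$periods), "period(s):",
      paste(x$periods, collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format survey table
#'
#' Reads a delimited text file with one row per (period, patch, species)
#' count. Column names are mapped through `dialect$col_map`; duplicate keys
#' are summed; the period order is first-appearance order unless
#' `dialect$period_order` overrides it.
#'
#' @param path file path.
#' @param dialect list of reader options: `sep` (default tab), `col_map`
#'   (named character vector mapping canonical field names to file column
#'   names), `period_order` (optional explicit period ordering).
#' @return A [survey_set()].
#' @export
read_survey_table <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (is.null(dialect$sep)) "\t" else dialect$sep
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character",
                           quote = "\"", comment.char = "")
  canonical <- c("period", "patch_id", "subregion", "species",
                 "functional_group", "count")
  col_map <- dialect$col_map
  if (is.null(col_map)) col_map <- stats::setNames(canonical, canonical)
  for (field in canonical) {
    src <- if (field %in% names(col_map)) col_map[[field]] else field
    if (!src %in% names(raw)) {
      stop("survey table is missing required column '", src,
           "' (field ", field, ")", call. = FALSE)
    }
  }
  records <- data.frame(
    period = raw[[col_map[["period"]]]],
    patch_id = raw[[col_map[["patch_id"]]]],
    subregion = raw[[col_map[["subregion"]]]],
    species = raw[[col_map[["species"]]]],
    functional_group = raw[[col_map[["functional_group"]]]],
    count = suppressWarnings(as.numeric(raw[[col_map[["count"]]]])),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(records$count) | records$count < 0)
  if (length(bad) > 0L) {
    stop("negative or unparseable count at data row ", bad[1L], call. = FALSE)
  }
  survey_set(records, periods = dialect$period_order)
}

#' Species-by-patch abundance matrix for one period
#'
#' @param s a [survey_set()].
#' @param period period label, must be one of `s$periods`.
#' @return Integer matrix (rows = species, columns = patches, lexicographic
#'   order) with attributes `period`; class `abundance_matrix`.
#' @export
to_abundance_matrix <- function(s, period) {
  stopifnot(inherits(s, "survey_set"))
  if (!period %in% s$periods) {
    stop("unknown period: ", period, call. = FALSE)
  }
  rec <- s$records[s$records$period == period, , drop = FALSE]
  species <- sort(unique(rec$species))
  patches <- sort(unique(rec$patch_id))
  m <- matrix(0, nrow = length(species), ncol = length(patches),
              dimnames = list(species, patches))
  if (nrow(rec) > 0L) {
    m[cbind(match(rec$species, species), match(rec$patch_id, patches))] <-
      rec$count
  }
  structure(m, period = period, class = c("abundance_matrix", "matrix"))
}

#' Write a result table as deterministic TSV
#'
#' Tab-separated, UTF-8, one header line. Rows are sorted by the leading key
#' columns so re-runs produce byte-identical files. Reals keep 12 significant
#' digits so a read-back round-trips.
#'
#' @param rows data frame (may have zero rows).
#' @param path output path.
#' @param sort_by columns to sort on; defaults to all non-numeric columns in
#'   their current order.
#' @export
write_table <- function(rows, path, sort_by = NULL) {
  rows <- as.data.frame(rows)
  if (nrow(rows) > 0L) {
    if (is.null(sort_by)) {
      sort_by <- names(rows)[!vapply(rows, is.numeric, logical(1L))]
    }
    if (length(sort_by) > 0L) {
      ord <- do.call(order, c(unname(rows[sort_by]), list(method = "radix")))
      rows <- rows[ord, , drop = FALSE]
    }
  }
  fmt <- rows
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) {
      fmt[[j]] <- vapply(fmt[[j]], function(v) {
        if (is.na(v)) "NA"
        else if (v == round(v) && abs(v) < 1e15) format(v, scientific = FALSE)
        else format(v, digits = 12, scientific = FALSE)
      }, character(1L))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(fmt), collapse = "\t"), con, sep = "\n")
  if (nrow(fmt) > 0L) {
    lines <- do.call(paste, c(unname(fmt), list(sep = "\t")))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a patch attribute table
#'
#' Expects at least `patch_id` and `wetland_area`; optional columns are
#' `water_area`, `mudflat_area`, `vegetation_area`, `disturbance`,
#' `protection`, `elevation`, `perimeter`, `surveyed`. Validates that
#' habitat areas do not exceed the wetland area by more than 5 percent.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return Data frame of patch attributes.
#' @export
read_patch_attributes <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("patch_id", "wetland_area") %in% names(tab))) {
    stop("patch table needs columns patch_id and wetland_area", call. = FALSE)
  }
  areas <- c("wetland_area", "water_area", "mudflat_area", "vegetation_area")
  for (a in intersect(areas, names(tab))) {
    if (any(tab[[a]] < 0, na.rm = TRUE)) {
      stop("negative area in column ", a, call. = FALSE)
    }
  }
  hab <- intersect(areas[-1L], names(tab))
  if (length(hab) == 3L) {
    total <- rowSums(tab[hab])
    over <- total > tab$wetland_area * 1.05
    if (any(over, na.rm = TRUE)) {
      stop("habitat areas exceed wetland area (+5% tolerance) for patch ",
           tab$patch_id[which(over)[1L]], call. = FALSE)
    }
  }
  tab
}

#' Read a daily water-level series
#'
#' Two-column delimited text (`date`, `level_m`). Dates must be strictly
#' increasing and daily.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return A `hydro_series`: list with `dates` (Date) and `levels` (numeric).
#' @export
read_hydro_series <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("water-level series needs two columns", call. = FALSE)
  hydro_series(as.Date(tab[[1L]]), as.numeric(tab[[2L]]))
}

#' Construct a daily water-level series
#'
#' @param dates Date vector, strictly increasing, daily.
#' @param levels numeric water levels (m), same length.
#' @return Object of class `hydro_series`.
#' @export
hydro_series <- function(dates, levels) {
  dates <- as.Date(dates)
  if (length(dates) != length(levels)) {
    stop("dates and levels differ in length", call. = FALSE)
  }
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L)) {
    stop("dates must be strictly increasing and daily", call. = FALSE)
  }
  structure(list(dates = dates, levels = as.numeric(levels)),
            class = "hydro_series")
}
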