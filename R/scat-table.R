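#' Construct a scat content table
#'
#' A scat table is a long-format `data.frame` with one row per prey item
#' found in a scat. Required columns are `scat_id`, `predator`,
#' `prey_taxon` and `volume_fraction`; `date` (class `Date`), `season`
#' (`"dry"`/`"rainy"`) and `diameter_cm` are optional and may be `NA`.
#' Within each scat the volume fractions must be positive and sum to 1,
#' and no prey taxon may appear twice.
#'
#' @param x a `data.frame` with at least the required columns.
#' @param renormalize if `TRUE`, per-scat volume fractions whose sum lies
#'   within 2% of 1 are rescaled to sum to exactly 1; sums outside
#'   `[0.98, 1.02]` are an error either way.
#' @return `x` with class `scat_table`, rows grouped by scat id in order
#'   of first appearance (within-scat order preserved).
#' @examples
#' scat_table(data.frame(
#'   scat_id = "S1", predator = "tiger",
#'   prey_taxon = c("wild_pig", "serow"),
#'   volume_fraction = c(0.7, 0.3)))
#' @export
scat_table <- function(x, renormalize = FALSE) {
  required <- c("scat_id", "predator", "prey_taxon", "volume_fraction")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop("scat table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$scat_id <- as.character(x$scat_id)
  x$predator <- as.character(x$predator)
  x$prey_taxon <- as.character(x$prey_taxon)
  x$volume_fraction <- as.numeric(x$volume_fraction)
  for (opt in c("date", "season", "diameter_cm"))
    if (!opt %in% names(x)) x[[opt]] <- NA
  if (!inherits(x$date, "Date")) x$date <- as.Date(x$date)
  x$diameter_cm <- as.numeric(x$diameter_cm)

  # group rows by scat id (stable), keeping within-scat input order
  x <- x[order(match(x$scat_id, unique(x$scat_id))), , drop = FALSE]
  rownames(x) <- NULL

  if (any(!nzchar(x$prey_taxon) | is.na(x$prey_taxon)))
    stop("empty prey taxon label", call. = FALSE)
  if (any(is.na(x$volume_fraction) | x$volume_fraction <= 0))
    stop("volume fractions must be positive", call. = FALSE)

  sums <- tapply_v(x$volume_fraction, x$scat_id, sum)
  if (renormalize) {
    bad <- names(sums)[sums < 0.98 | sums > 1.02]
    if (length(bad) > 0)
      stop("volume fractions of scat(s) ", paste(bad, collapse = ", "),
           " sum outside [0.98, 1.02]", call. = FALSE)
    x$volume_fraction <- unname(x$volume_fraction / sums[x$scat_id])
  } else {
    bad <- names(sums)[abs(sums - 1) > 1e-9]
    if (length(bad) > 0)
      stop("volume fractions of scat(s) ", paste(bad, collapse = ", "),
           " do not sum to 1", call. = FALSE)
  }

  dup <- vapply(split(x$prey_taxon, x$scat_id), anyDuplicated, 0) > 0
  if (any(dup))
    stop("duplicated prey taxon within scat(s): ",
         paste(names(dup)[dup], collapse = ", "), call. = FALSE)
  npred <- tapply(x$predator, x$scat_id, function(p) length(unique(p)))
  if (any(npred > 1))
    stop("conflicting predator labels within scat(s): ",
         paste(names(npred)[npred > 1], collapse = ", "), call. = FALSE)

  class(x) <- c("scat_table", "data.frame")
  x
}

#' Number of scats in a scat table
#' @param x a [scat_table()].
#' @return integer count of distinct scats.
#' @export
n_scats <- function(x) length(unique(x$scat_id))

#' @export
print.scat_table <- function(x, ...) {
  cat(sprintf("Scat content table: %d scat(s), %d prey item row(s), predator(s): %s\n",
              n_scats(x), nrow(x),
              paste(unique(x$predator), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a scat content table from CSV
#'
#' Reads a long-format UTF-8 CSV (header row required, one prey item per
#' row) into a validated [scat_table()]. Per-scat volume fractions that
#' sum to within 2% of 1 are renormalized to sum to exactly 1; sums
#' outside `[0.98, 1.02]` raise an error naming the offending scat.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping standard column
#'   names (`scat_id`, `predator`, `prey_taxon`, `volume_fraction`,
#'   `date`, `diameter_cm`) to the column names used in the file.
#' @param known_predators optional character vector; if supplied, any
#'   predator label outside this set is an error.
#' @return a [scat_table()]; `season` is derived from `date` with
#'   [assign_season()] where dates are present.
#' @seealso [write_scat_table()]
#' @export
read_scat_table <- function(path, schema = NULL, known_predators = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(raw))
        stop("schema column '", schema[[std]], "' not present in file",
             call. = FALSE)
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  required <- c("scat_id", "predator", "prey_taxon", "volume_fraction")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.null(known_predators)) {
    unknown <- setdiff(unique(raw$predator), known_predators)
    if (length(unknown) > 0)
      stop("unknown predator label(s): ", paste(unknown, collapse = ", "),
           "; known: ", paste(known_predators, collapse = ", "),
           call. = FALSE)
  }
  x <- scat_table(raw, renormalize = TRUE)
  if (any(!is.na(x$date)))
    x$season <- ifelse(is.na(x$date), NA_character_, assign_season(x$date))
  x
}

#' Write a scat content table to CSV
#'
#' Volume fractions are written at full double precision so that a
#' write/read round trip is the identity on scat id, predator, taxon and
#' volume fraction.
#'
#' @param x a [scat_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scat_table <- function(x, path) {
  out <- as.data.frame(x)
  out$volume_fraction <- vapply(out$volume_fraction, format, "",
                                digits = 17)
  utils::write.csv(
    out[, c("scat_id", "predator", "date", "diameter_cm",
            "prey_taxon", "volume_fraction")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign the monsoon season of a collection date
#'
#' The study area has two seasons: rainy from 15 May to 31 October
#' (inclusive) and dry from 1 November to 14 May.
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts).
#' @return character vector of `"dry"` / `"rainy"`.
#' @examples
#' assign_season(as.Date(c("2009-06-01", "2009-12-01", "2009-05-15")))
#' @export
assign_season <- function(date) {
  date <- as.Date(date)
  if (any(is.na(date))) stop("invalid date", call. = FALSE)
  md <- as.integer(format(date, "%m")) * 100 + as.integer(format(date, "%d"))
  ifelse(md >= 515 & md <= 1031, "rainy", "dry")
}

# tapply that returns a plain named numeric vector
tapply_v <- function(x, by, fun) {
  a <- tapply(x, by, fun)
  stats::setNames(as.numeric(a), names(a))
}
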