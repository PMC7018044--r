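#' Read occurrence records from CSV
#'
#' Expects header columns `species`, `x`, `y` and optionally `date` (ISO
#' `YYYY-MM-DD`) and `source`. Rows belonging to other species are excluded.
#' Rows whose mandatory fields cannot be parsed (empty species, non-numeric
#' coordinates) are not silently dropped: they are returned in the
#' `"rejected"` attribute with their 1-based data row number and a reason.
#'
#' @param path CSV path.
#' @param species target species name, or `NULL` to keep all species.
#' @return data.frame with columns `species`, `x`, `y`, `date` (`Date`),
#'   `source`; attribute `rejected` is a data.frame (`row`, `reason`).
#' @export
read_occurrences <- function(path, species = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("species", "x", "y")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop(sprintf("occurrence CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"date" %in% names(raw)) raw$date <- NA_character_
  if (!"source" %in% names(raw)) raw$source <- NA_character_

  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  sp <- trimws(raw$species)
  bad <- character(nrow(raw))
  bad[!nzchar(sp)] <- "empty species"
  bad[nzchar(sp) & (is.na(x) | !nzchar(trimws(raw$x)))] <- "unparseable x"
  bad[nzchar(sp) & !is.na(x) & (is.na(y) | !nzchar(trimws(raw$y)))] <-
    "unparseable y"
  rejected <- data.frame(row = which(nzchar(bad)),
                         reason = bad[nzchar(bad)],
                         stringsAsFactors = FALSE)
  keep <- !nzchar(bad)
  if (!is.null(species)) keep <- keep & sp == species
  out <- data.frame(
    species = sp[keep], x = x[keep], y = y[keep],
    date = as.Date(ifelse(nzchar(trimws(raw$date[keep])), raw$date[keep],
                          NA_character_)),
    source = raw$source[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- rejected
  out
}

#' Write occurrence records to CSV
#'
#' Inverse of [read_occurrences()]; coordinates are written with full
#' double precision so that write-then-read round-trips exactly.
#'
#' @param records data.frame with columns `species`, `x`, `y`, `date`,
#'   `source`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  out <- data.frame(
    species = records$species,
    x = sprintf("%.17g", records$x),
    y = sprintf("%.17g", records$y),
    date = ifelse(is.na(records$date), "", as.character(records$date)),
    source = ifelse(is.na(records$source), "", records$source),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
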