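#' Construct a measurement table
#'
#' A `measurement_table` is the central container of the package: a
#' specimens-by-characters matrix of lengths in micrometres with a unique
#' specimen identifier, a group (OTU/species) label, an optional strain
#' (sub-group) label, and two boolean masks of the same shape recording
#' which cells are missing and which have been imputed.
#'
#' @param values numeric matrix, one row per specimen, one column per
#'   character; columns named with registered character abbreviations.
#'   `NA` entries mark missing measurements; all observed values must be
#'   strictly positive and finite.
#' @param specimen_id character vector of unique specimen identifiers.
#' @param group character vector of group (OTU) labels, one per specimen.
#' @param strain optional character vector of strain labels (`NA` allowed).
#' @param registry character registry as returned by
#'   [character_registry()]; columns of `values` must be a subset of its
#'   abbreviations.
#' @param imputed_mask logical matrix marking imputed cells; defaults to
#'   all-`FALSE`. Imputed cells must be a subset of originally missing
#'   cells; bookkeeping is maintained by [impute_missing()].
#' @return An object of class `measurement_table`.
#' @seealso [read_measurement_table()], [drop_variables()],
#'   [impute_missing()]
#' @export
measurement_table <- function(values, specimen_id, group, strain = NULL,
                              registry = character_registry(),
                              imputed_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(colnames(values)))
    stop("'values' must have column names (character abbreviations)")
  unknown <- setdiff(colnames(values), registry$abbreviation)
  if (length(unknown))
    stop("unregistered character column(s): ", paste(unknown, collapse = ", "))
  specimen_id <- as.character(specimen_id)
  if (length(specimen_id) != n)
    stop("'specimen_id' length must match nrow(values)")
  if (anyDuplicated(specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "))
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n) stop("'group' length must match nrow(values)")
  if (is.null(strain)) strain <- rep(NA_character_, n)
  strain <- as.character(strain)
  if (length(strain) == 1L) strain <- rep(strain, n)
  bad <- which(!is.na(values) & (values <= 0 | !is.finite(values)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive or non-finite measurement at specimen '",
         specimen_id[bad[1, 1]], "', character '",
         colnames(values)[bad[1, 2]], "'")
  missing_mask <- is.na(values)
  if (is.null(imputed_mask)) {
    imputed_mask <- matrix(FALSE, n, ncol(values),
                           dimnames = dimnames(values))
  } else {
    imputed_mask <- as.matrix(imputed_mask)
    stopifnot(identical(dim(imputed_mask), dim(values)))
    dimnames(imputed_mask) <- dimnames(values)
  }
  rownames(values) <- rownames(missing_mask) <- rownames(imputed_mask) <-
    specimen_id
  structure(
    list(values = values, specimen_id = specimen_id, group = group,
         strain = strain, missing_mask = missing_mask,
         imputed_mask = imputed_mask, registry = registry),
    class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("Measurement table:", nrow(x$values), "specimens x",
      ncol(x$values), "characters (um)\n")
  cat("Groups:", paste(sprintf("%s (%d)", names(table(x$group)),
                               table(x$group)), collapse = ", "), "\n")
  nmiss <- sum(x$missing_mask & !x$imputed_mask)
  nimp <- sum(x$imputed_mask)
  cat("Missing cells:", nmiss, "| imputed cells:", nimp, "\n")
  invisible(x)
}

#' @export
dim.measurement_table <- function(x) dim(x$values)

#' Read a measurement table from a delimited text file
#'
#' Reads a UTF-8 comma-delimited file with a header row. The columns
#' `specimen_id`, `group` and (optionally) `strain` are followed by one
#' column per measured character, named with its registered abbreviation
#' and holding lengths in micrometres. Empty cells and the sentinels
#' `"NA"`/`"NaN"` (case-insensitive) are read as missing. Unknown columns
#' beyond id/group/strain raise a warning and are dropped.
#'
#' @param path path to a CSV file (decimal point ".", comma delimiter).
#' @param registry character registry; see [character_registry()].
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path, registry = character_registry()) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!"specimen_id" %in% names(raw)) stop("missing 'specimen_id' column")
  if (!"group" %in% names(raw)) stop("missing 'group' column")
  meta_cols <- intersect(c("specimen_id", "group", "strain"), names(raw))
  meas_cols <- setdiff(names(raw), meta_cols)
  unknown <- setdiff(meas_cols, registry$abbreviation)
  if (length(unknown)) {
    warning("ignoring unregistered column(s): ",
            paste(unknown, collapse = ", "))
    meas_cols <- setdiff(meas_cols, unknown)
  }
  vals <- matrix(NA_real_, nrow(raw), length(meas_cols),
                 dimnames = list(NULL, meas_cols))
  for (j in seq_along(meas_cols)) {
    cell <- trimws(raw[[meas_cols[j]]])
    is_na <- cell == "" | tolower(cell) %in% c("na", "nan")
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_na & is.na(num)
    if (any(bad))
      stop("non-numeric value '", cell[which(bad)[1]], "' at row ",
           which(bad)[1], ", column '", meas_cols[j], "'")
    num[is_na] <- NA_real_
    vals[, j] <- num
  }
  measurement_table(vals, specimen_id = raw$specimen_id, group = raw$group,
                    strain = if ("strain" %in% names(raw)) raw$strain,
                    registry = registry)
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurement_table()]: writes `specimen_id`, `group`,
#' `strain` and the measurement columns; missing cells become empty fields.
#'
#' @param table a [measurement_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  df <- data.frame(specimen_id = table$specimen_id, group = table$group,
                   strain = table$strain, check.names = FALSE,
                   stringsAsFactors = FALSE)
  # %.17g guarantees doubles survive a write -> read round trip exactly
  vals <- as.data.frame(table$values, check.names = FALSE)
  vals[] <- lapply(vals, function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  df <- cbind(df, vals)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop measurement variables from a table
#'
#' Removes columns (e.g. a damaged character such as gaster breadth) from a
#' measurement table; all masks subset consistently.
#'
#' @param table a [measurement_table()].
#' @param names character vector of abbreviations to drop; may be empty.
#' @return The table without those columns.
#' @export
drop_variables <- function(table, names) {
  stopifnot(inherits(table, "measurement_table"))
  if (length(names) == 0L) return(table)
  unknown <- setdiff(names, colnames(table$values))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(table$values), names)
  table$values <- table$values[, keep, drop = FALSE]
  table$missing_mask <- table$missing_mask[, keep, drop = FALSE]
  table$imputed_mask <- table$imputed_mask[, keep, drop = FALSE]
  table
}

# internal: rows of `table` restricted to specimens in a label set
.subset_specimens <- function(table, idx) {
  table$values <- table$values[idx, , drop = FALSE]
  table$specimen_id <- table$specimen_id[idx]
  table$group <- table$group[idx]
  table$strain <- table$strain[idx]
  table$missing_mask <- table$missing_mask[idx, , drop = FALSE]
  table$imputed_mask <- table$imputed_mask[idx, , drop = FALSE]
  table
}
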