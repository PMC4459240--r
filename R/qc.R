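#' Quality control of measurement variables by pairwise log-correlations
#'
#' Body measurements of closely related taxa are expected to correlate
#' positively and strongly, because a shared size factor dominates the
#' variation. A variable that correlates weakly with the rest is a sign of
#' measurement error or a morphological artifact (e.g. a collapsed gaster
#' inflating/deflating gaster breadth). This check computes Pearson
#' product-moment correlations between all pairs of natural-log
#' measurements, using pairwise-complete observations, and flags every
#' variable whose median off-diagonal correlation falls below `threshold`.
#' A zero-variance variable has undefined correlations and is flagged with
#' reason `"constant"`.
#'
#' @param table a [measurement_table()].
#' @param threshold flagging threshold in (0, 1); default 0.5. A variable
#'   is flagged when the median of its correlations with all other
#'   variables is below this value.
#' @return An object of class `mra_qc`: a list with `correlation_matrix`
#'   (p x p, unit diagonal), `per_variable_summary` (data frame of
#'   min/median/max off-diagonal correlation per variable),
#'   `flagged_variables`, `flag_reason` and `threshold`.
#' @examples
#' cfg <- synthetic_config(p = 6, groups = list(list(label = "A", n = 30)),
#'                         seed = 1)
#' tab <- simulate_measurements(cfg)$table
#' correlation_qc(tab)
#' @export
correlation_qc <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "measurement_table"))
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  logv <- log(table$values)
  p <- ncol(logv)
  if (p < 2L) stop("need at least two variables for correlation QC")
  nn <- crossprod(!is.na(logv))
  if (any(nn[upper.tri(nn)] < 3L))
    warning("fewer than 3 complete pairs for some variable pair(s); ",
            "correlations there are unreliable")
  sds <- apply(logv, 2, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  cm <- suppressWarnings(
    stats::cor(logv, use = "pairwise.complete.obs", method = "pearson"))
  diag(cm) <- 1
  off <- cm
  diag(off) <- NA
  summ <- data.frame(
    variable = colnames(logv),
    min = apply(off, 2, min, na.rm = TRUE),
    median = apply(off, 2, stats::median, na.rm = TRUE),
    max = apply(off, 2, max, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  flagged_low <- summ$variable[!is.na(summ$median) & summ$median < threshold]
  flagged <- union(colnames(logv)[constant], flagged_low)
  reason <- ifelse(flagged %in% colnames(logv)[constant], "constant",
                   "low median correlation")
  structure(list(correlation_matrix = cm,
                 per_variable_summary = summ,
                 flagged_variables = flagged,
                 flag_reason = stats::setNames(reason, flagged),
                 threshold = threshold),
            class = "mra_qc")
}

#' @export
print.mra_qc <- function(x, ...) {
  cat("Measurement QC (Pearson correlations of log-measurements)\n")
  cat("Threshold on median off-diagonal r:", x$threshold, "\n")
  if (length(x$flagged_variables)) {
    cat("Flagged:", paste(sprintf("%s [%s]", x$flagged_variables,
                                  x$flag_reason), collapse = ", "), "\n")
  } else cat("Flagged: none\n")
  invisible(x)
}

#' Write a QC report as TSV plus a plain-text summary
#'
#' @param qc an `mra_qc` object from [correlation_qc()].
#' @param path base path; writes `<path>.tsv` (per-variable summary) and
#'   `<path>.txt` (summary lines).
#' @return The two paths, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "mra_qc"))
  tsv <- paste0(path, ".tsv")
  txt <- paste0(path, ".txt")
  df <- qc$per_variable_summary
  df$flagged <- df$variable %in% qc$flagged_variables
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c(sprintf("threshold\t%g", qc$threshold),
             sprintf("flagged\t%s",
                     paste(qc$flagged_variables, collapse = ",")))
  writeLines(lines, txt)
  invisible(c(tsv, txt))
}
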