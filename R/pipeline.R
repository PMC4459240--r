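#' Configuration for the full ratio-analysis pipeline
#'
#' @param input path to a measurement CSV, or a [measurement_table()].
#' @param out_dir output directory (created if absent).
#' @param qc_threshold QC flagging threshold (see [correlation_qc()]).
#' @param drop variables to force-drop in addition to QC-flagged ones.
#' @param drop_flagged drop QC-flagged variables automatically?
#' @param comparisons list of [group_comparison()] objects (may be empty,
#'   in which case the pipeline stops after the spectra with a notice).
#' @param n_ratios ratios per comparison.
#' @param n_boot,level bootstrap settings for the spectra.
#' @param pcs shape PCs for which to write a PCA ratio spectrum.
#' @param run_key classify every specimen with the identification key?
#'   Only meaningful when the table carries all key characters.
#' @param seed integer seed, recorded in every output header.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, qc_threshold = 0.5,
                            drop = character(), drop_flagged = TRUE,
                            comparisons = list(), n_ratios = 2,
                            n_boot = 1000, level = 0.68, pcs = 1,
                            run_key = FALSE, seed = 1L) {
  structure(list(input = input, out_dir = out_dir,
                 qc_threshold = qc_threshold, drop = drop,
                 drop_flagged = drop_flagged, comparisons = comparisons,
                 n_ratios = n_ratios, n_boot = n_boot, level = level,
                 pcs = pcs, run_key = run_key, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full ratio-analysis pipeline
#'
#' Orchestrates the analysis sequence: read and validate the table,
#' correlation QC, drop damaged variables, impute missing values, size/
#' shape decomposition, shape PCA, PCA and allometry ratio spectra, best-
#' ratio extraction per comparison, and (optionally) key classification.
#' Writes `qc.tsv`/`qc.txt`, `imputation_log.tsv`, `shape_scores.tsv`,
#' `spectra/*.tsv`, `table2_report.tsv`, `key_results.tsv` and
#' `run_log.txt` to the output directory. Every stage is a pure function
#' of (inputs, config, seed): re-running with identical inputs reproduces
#' byte-identical numeric outputs. A stage failure aborts with the stage
#' name and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`table`,
#'   `qc`, `imputation`, `shape`, `pca`, `spectra`, `report`, `key`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  out <- function(...) file.path(config$out_dir, ...)
  res <- list()
  tryCatch({
    stage <- "read"
    tab <- if (inherits(config$input, "measurement_table")) config$input
           else read_measurement_table(config$input)
    stage <- "qc"
    qc <- correlation_qc(tab, threshold = config$qc_threshold)
    written <- c(written, write_qc_report(qc, out("qc")))
    stage <- "drop"
    to_drop <- union(config$drop,
                     if (config$drop_flagged) qc$flagged_variables)
    to_drop <- intersect(to_drop, colnames(tab$values))
    tab <- drop_variables(tab, to_drop)
    stage <- "impute"
    imp <- impute_missing(tab, seed = config$seed)
    tab <- imp$table
    written <- c(written,
                 write_imputation_log(imp$log, out("imputation_log.tsv")))
    stage <- "shape"
    sh <- shape_decompose(tab)
    pca <- shape_pca(sh)
    sc <- data.frame(specimen_id = sh$specimen_id, group = sh$group,
                     isosize = sh$isosize,
                     pca$scores[, seq_len(min(4, ncol(pca$scores))),
                                drop = FALSE],
                     check.names = FALSE)
    f <- out("shape_scores.tsv")
    .write_tsv_commented(sc, f, config)
    written <- c(written, f)
    stage <- "spectra"
    dir.create(out("spectra"), showWarnings = FALSE)
    spectra <- list()
    for (pc in config$pcs) {
      sp <- pca_ratio_spectrum(pca, pc = pc, shape = sh,
                               n_boot = config$n_boot,
                               level = config$level, seed = config$seed)
      f <- out("spectra", sprintf("pca_pc%d.tsv", pc))
      write_spectrum(sp, f)
      written <- c(written, f)
      spectra[[sp$axis_tag]] <- sp
    }
    asp <- allometry_ratio_spectrum(sh, n_boot = config$n_boot,
                                    level = config$level,
                                    seed = config$seed)
    f <- out("spectra", "allometry.tsv")
    write_spectrum(asp, f)
    written <- c(written, f)
    spectra$allometry <- asp
    res <- list(table = tab, qc = qc, imputation = imp$log, shape = sh,
                pca = pca, spectra = spectra)
    stage <- "extract"
    if (length(config$comparisons) == 0L) {
      writeLines(c(.log_lines(config),
                   "notice: empty comparisons list; stopped after spectra"),
                 out("run_log.txt"))
      return(invisible(res))
    }
    report <- table2_report(tab, config$comparisons,
                            n_ratios = config$n_ratios)
    f <- out("table2_report.tsv")
    .write_tsv_commented(report, f, config)
    written <- c(written, f)
    res$report <- report
    stage <- "key"
    if (config$run_key) {
      key <- do.call(rbind, lapply(seq_len(nrow(tab$values)), function(i) {
        r <- compute_ratios(tab$values[i, ])
        k <- key_classify(r)
        data.frame(specimen_id = tab$specimen_id[i], group = tab$group[i],
                   label = k$label,
                   trace = paste(k$trace$couplet,
                                 ifelse(is.na(k$trace$branch), "?",
                                        k$trace$branch),
                                 sep = "", collapse = ">"),
                   stringsAsFactors = FALSE)
      }))
      f <- out("key_results.tsv")
      .write_tsv_commented(key, f, config)
      written <- c(written, f)
      res$key <- key
    }
    writeLines(.log_lines(config), out("run_log.txt"))
    invisible(res)
  }, error = on_fail)
}

# internal: TSV with a commented parameter header
.write_tsv_commented <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d qc_threshold=%g n_boot=%d level=%g",
                     config$seed, config$qc_threshold, config$n_boot,
                     config$level), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.log_lines <- function(config) {
  c(sprintf("mratio %s | R %s", as.character(utils::packageVersion("mratio")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed=%d", config$seed),
    sprintf("qc_threshold=%g", config$qc_threshold),
    sprintf("drop=%s", paste(config$drop, collapse = ",")),
    sprintf("n_ratios=%d n_boot=%d level=%g", config$n_ratios,
            config$n_boot, config$level))
}
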