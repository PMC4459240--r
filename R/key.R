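#' Ratios used by the identification key and species diagnoses
#'
#' Computes, from a named vector of measurements (micrometres), every
#' body ratio referenced by the female identification key and the species
#' diagnoses of *Anisopteromalus*.
#'
#' @param measurements named numeric vector (or one-row matrix) of
#'   measurements with registered abbreviations as names.
#' @return Named numeric vector of ratios, e.g. `"hea.b:tb3.l"`.
#' @examples
#' compute_ratios(c(hea.b = 1530, tb3.l = 1000))[["hea.b:tb3.l"]]  # 1.53
#' @export
compute_ratios <- function(measurements) {
  m <- drop(as.matrix(measurements))
  if (is.matrix(m)) m <- m[1, ]
  defs <- key_ratio_definitions()
  need <- unique(c(defs$numerator, defs$denominator))
  have <- need %in% names(m) & !is.na(m[need])
  out <- rep(NA_real_, nrow(defs))
  names(out) <- defs$ratio
  for (i in seq_len(nrow(defs))) {
    a <- defs$numerator[i]; b <- defs$denominator[i]
    if (a %in% names(m) && b %in% names(m) &&
        !is.na(m[[a]]) && !is.na(m[[b]]))
      out[i] <- m[[a]] / m[[b]]
  }
  if (anyNA(out)) {
    missing <- unique(unlist(
      defs[is.na(out), c("numerator", "denominator")]))
    missing <- setdiff(missing, names(m)[!is.na(m)])
    stop("missing character(s) required by the key: ",
         paste(missing, collapse = ", "))
  }
  out
}

#' Definitions of the key/diagnosis ratios
#'
#' @return Data frame with columns `ratio`, `numerator`, `denominator`.
#' @export
key_ratio_definitions <- function() {
  num <- c("hea.b", "eye.h", "mss.l", "hea.b", "pdl.flg", "hea.h",
           "tb3.l", "sct.l", "gst.l")
  den <- c("tb3.l", "sct.l", "ool.l", "eye.d", "eye.h", "eye.b",
           "mv.l", "stv.l", "ool.l")
  data.frame(ratio = paste0(num, ":", den), numerator = num,
             denominator = den, stringsAsFactors = FALSE)
}

# One quantitative condition on a named ratio. op: ge/le/gt/lt/range.
.cond <- function(ratio, op, lo, hi = NA) {
  list(ratio = ratio, op = op, lo = lo, hi = hi)
}

.cond_holds <- function(cond, ratios) {
  v <- ratios[[cond$ratio]]
  switch(cond$op,
         ge = v >= cond$lo, le = v <= cond$lo,
         gt = v > cond$lo, lt = v < cond$lo,
         range = v >= cond$lo && v <= cond$hi,
         stop("unknown op ", cond$op))
}

.cond_label <- function(cond) {
  switch(cond$op,
         ge = sprintf("%s >= %g", cond$ratio, cond$lo),
         le = sprintf("%s <= %g", cond$ratio, cond$lo),
         gt = sprintf("%s > %g", cond$ratio, cond$lo),
         lt = sprintf("%s < %g", cond$ratio, cond$lo),
         range = sprintf("%s in [%g, %g]", cond$ratio, cond$lo, cond$hi))
}

#' Definition of the dichotomous key to Anisopteromalus females
#'
#' Five couplets; each branch combines quantitative ratio thresholds
#' (conjunction or disjunction) with optional qualitative trait
#' requirements, and leads to a species or to the next couplet. The point
#' values printed for the single known *A. ceylonensis* specimen
#' (`hea.h:eye.b` 2.02, `tb3.l:mv.l` 1.56) are encoded as bands of width
#' +/- 0.05.
#'
#' @return A list of couplets (used by [key_classify()]); each couplet
#'   has `id` and two branches with `conditions`, `combine` ("and"/"or"),
#'   `traits` (named logical) and `outcome` (species label or next
#'   couplet id).
#' @export
key_definition <- function() {
  list(
    list(id = 1L,
         a = list(conditions = list(.cond("hea.b:tb3.l", "ge", 1.53),
                                    .cond("eye.h:sct.l", "le", 1.10)),
                  combine = "and",
                  traits = c(speculum_setose = TRUE,
                             scutellum_projecting = TRUE),
                  outcome = "apiovorus"),
         b = list(conditions = list(.cond("hea.b:tb3.l", "lt", 1.53),
                                    .cond("eye.h:sct.l", "gt", 1.10)),
                  combine = "or",
                  traits = c(speculum_setose = FALSE,
                             scutellum_projecting = FALSE),
                  outcome = 2L)),
    list(id = 2L,
         a = list(conditions = list(.cond("mss.l:ool.l", "le", 8.14),
                                    .cond("hea.b:eye.d", "le", 1.52)),
                  combine = "and",
                  traits = c(tergite1_produced = TRUE),
                  outcome = 3L),
         b = list(conditions = list(.cond("mss.l:ool.l", "gt", 8.14),
                                    .cond("hea.b:eye.d", "gt", 1.52)),
                  combine = "or",
                  traits = c(tergite1_produced = FALSE),
                  outcome = 4L)),
    list(id = 3L,
         a = list(conditions = list(.cond("pdl.flg:eye.h", "range",
                                          1.77, 2.25)),
                  combine = "and",
                  traits = c(flagellum_clavate = TRUE,
                             mesosoma_blue = FALSE),
                  outcome = "calandrae"),
         b = list(conditions = list(.cond("pdl.flg:eye.h", "range",
                                          2.43, 2.69)),
                  combine = "and",
                  traits = c(flagellum_clavate = FALSE,
                             mesosoma_blue = TRUE),
                  outcome = "cornis")),
    list(id = 4L,
         a = list(conditions = list(.cond("hea.h:eye.b", "range",
                                          2.02 - 0.05, 2.02 + 0.05),
                                    .cond("tb3.l:mv.l", "range",
                                          1.56 - 0.05, 1.56 + 0.05)),
                  combine = "and",
                  traits = c(scutellum_strongly_curved = TRUE),
                  outcome = "ceylonensis"),
         b = list(conditions = list(.cond("hea.h:eye.b", "range",
                                          2.24, 2.74),
                                    .cond("tb3.l:mv.l", "range",
                                          1.67, 2.25)),
                  combine = "and",
                  traits = c(scutellum_strongly_curved = FALSE),
                  outcome = 5L)),
    list(id = 5L,
         a = list(conditions = list(.cond("sct.l:stv.l", "le", 2.00),
                                    .cond("gst.l:ool.l", "ge", 11.38)),
                  combine = "and",
                  traits = c(gena_carinate = TRUE),
                  outcome = "quinarius"),
         b = list(conditions = list(.cond("sct.l:stv.l", "gt", 2.00),
                                    .cond("gst.l:ool.l", "lt", 11.38)),
                  combine = "or",
                  traits = c(gena_carinate = FALSE),
                  outcome = "caryedophagus"))
  )
}

# internal: does a branch's quantitative part hold?
.branch_quant <- function(branch, ratios) {
  hold <- vapply(branch$conditions, .cond_holds, TRUE, ratios = ratios)
  if (branch$combine == "and") all(hold) else any(hold)
}

# internal: do supplied traits match a branch's requirements?
# Returns NA when no relevant trait supplied.
.branch_traits <- function(branch, traits) {
  if (is.null(traits) || !length(branch$traits)) return(NA)
  shared <- intersect(names(branch$traits), names(traits))
  if (!length(shared)) return(NA)
  all(unlist(traits[shared]) == branch$traits[shared])
}

#' Classify a specimen with the dichotomous key
#'
#' Walks the key from couplet 1. Quantitative ratio thresholds decide
#' each couplet; when the quantitative conditions of both branches fail —
#' the specimen falls in a gap between printed ranges — the couplet is
#' resolved by supplied qualitative traits if they unambiguously match
#' one branch, and otherwise the result is `"indeterminate"`. The key
#' never guesses. Qualitative traits that match both branches (or
#' conflict between branches) raise an error.
#'
#' @param ratios named ratio vector from [compute_ratios()].
#' @param traits optional named logical list/vector of qualitative traits
#'   (e.g. `speculum_setose`, `gena_carinate`, `flagellum_clavate`,
#'   `tergite1_produced`, `scutellum_strongly_curved`).
#' @return An object of class `key_result`: `label` (species or
#'   "indeterminate"), `trace` (data frame of couplet decisions), and
#'   `unmet` (conditions that failed at an unresolved couplet; non-empty
#'   iff indeterminate).
#' @export
key_classify <- function(ratios, traits = NULL) {
  key <- key_definition()
  trace <- data.frame(couplet = integer(), branch = character(),
                      decided_by = character(), stringsAsFactors = FALSE)
  unmet <- character()
  cur <- 1L
  repeat {
    cp <- key[[cur]]
    qa <- .branch_quant(cp$a, ratios)
    qb <- .branch_quant(cp$b, ratios)
    if (qa && !qb) {
      pick <- "a"; by <- "quantitative"
    } else if (qb && !qa) {
      pick <- "b"; by <- "quantitative"
    } else if (qa && qb) {
      # overlapping printed ranges: resolve by traits, else indeterminate
      pick <- .resolve_by_traits(cp, traits)
      by <- "qualitative"
    } else {
      pick <- .resolve_by_traits(cp, traits)
      by <- "qualitative"
    }
    if (is.na(pick)) {
      unmet <- c(vapply(cp$a$conditions, .cond_label, ""),
                 vapply(cp$b$conditions, .cond_label, ""))
      trace <- rbind(trace, data.frame(couplet = cp$id, branch = NA,
                                       decided_by = "unresolved"))
      return(structure(list(label = "indeterminate", trace = trace,
                            unmet = unmet), class = "key_result"))
    }
    trace <- rbind(trace, data.frame(couplet = cp$id, branch = pick,
                                     decided_by = by))
    outcome <- if (pick == "a") cp$a$outcome else cp$b$outcome
    if (is.character(outcome))
      return(structure(list(label = outcome, trace = trace,
                            unmet = character()), class = "key_result"))
    cur <- outcome
  }
}

# internal: qualitative resolution of a couplet; NA if undecidable.
# Each supplied trait shared with the couplet supports one branch (its
# value matches that branch's requirement); mixed support is contradictory.
.resolve_by_traits <- function(cp, traits) {
  if (is.null(traits)) return(NA_character_)
  shared <- intersect(names(cp$a$traits), names(traits))
  if (!length(shared)) return(NA_character_)
  support_a <- unlist(traits[shared]) == cp$a$traits[shared]
  if (all(support_a)) return("a")
  if (all(!support_a)) return("b")
  stop("contradictory qualitative traits at couplet ", cp$id, ": ",
       paste(shared, collapse = ", "))
}

#' @export
print.key_result <- function(x, ...) {
  cat("Key classification:", x$label, "\n")
  path <- apply(x$trace, 1, function(r)
    paste0(r[["couplet"]], if (!is.na(r[["branch"]])) r[["branch"]]))
  cat("Trace:", paste(path, collapse = " -> "), "\n")
  if (length(x$unmet))
    cat("Unmet conditions:\n ", paste(x$unmet, collapse = "\n  "), "\n")
  invisible(x)
}

#' Printed diagnostic ratio ranges per species
#'
#' Full diagnoses (nine ratio ranges) are available for *A. calandrae*,
#' *A. cornis* and *A. quinarius*.
#'
#' @param species one of `"calandrae"`, `"cornis"`, `"quinarius"`.
#' @return Data frame with columns `ratio`, `lo`, `hi`.
#' @export
diagnosis_ranges <- function(species) {
  ranges <- list(
    calandrae = rbind(
      c("hea.b:tb3.l", 1.24, 1.51), c("hea.b:eye.d", 1.38, 1.52),
      c("hea.h:eye.b", 2.46, 3.39), c("eye.h:sct.l", 1.09, 1.30),
      c("pdl.flg:eye.h", 1.77, 2.25), c("mss.l:ool.l", 5.96, 8.14),
      c("sct.l:stv.l", 1.48, 1.96), c("tb3.l:mv.l", 1.66, 2.21),
      c("gst.l:ool.l", 7.78, 12.02)),
    cornis = rbind(
      c("hea.b:tb3.l", 1.15, 1.26), c("hea.b:eye.d", 1.37, 1.40),
      c("hea.h:eye.b", 3.15, 3.59), c("eye.h:sct.l", 1.05, 1.09),
      c("pdl.flg:eye.h", 2.43, 2.69), c("mss.l:ool.l", 6.19, 7.96),
      c("sct.l:stv.l", 1.64, 1.74), c("tb3.l:mv.l", 1.90, 2.29),
      c("gst.l:ool.l", 7.98, 11.94)),
    quinarius = rbind(
      c("hea.b:tb3.l", 1.24, 1.51), c("hea.b:eye.d", 1.48, 1.69),
      c("hea.h:eye.b", 2.34, 2.74), c("eye.h:sct.l", 1.09, 1.32),
      c("pdl.flg:eye.h", 1.63, 1.97), c("mss.l:ool.l", 8.11, 11.87),
      c("sct.l:stv.l", 1.38, 2.00), c("tb3.l:mv.l", 1.67, 2.25),
      c("gst.l:ool.l", 11.38, 16.43)))
  if (!species %in% names(ranges))
    stop("no built-in diagnosis for species '", species,
         "'; supply ranges explicitly")
  m <- ranges[[species]]
  data.frame(ratio = m[, 1], lo = as.numeric(m[, 2]),
             hi = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

#' Check a specimen's ratios against a species diagnosis
#'
#' For each diagnostic ratio range of the species, reports whether the
#' specimen's value falls inside.
#'
#' @param ratios named ratio vector from [compute_ratios()]; must be
#'   non-empty.
#' @param species species label with a built-in diagnosis (see
#'   [diagnosis_ranges()]), unless `ranges` is supplied.
#' @param ranges optional data frame (`ratio`, `lo`, `hi`) overriding the
#'   built-in diagnosis.
#' @return Data frame with columns `ratio`, `value`, `lo`, `hi`, `pass`.
#' @export
diagnosis_check <- function(ratios, species, ranges = NULL) {
  if (length(ratios) == 0L) stop("empty ratio set")
  if (is.null(ranges)) ranges <- diagnosis_ranges(species)
  value <- vapply(ranges$ratio, function(r) {
    if (!r %in% names(ratios)) NA_real_ else ratios[[r]]
  }, 0)
  data.frame(ratio = ranges$ratio, value = value, lo = ranges$lo,
             hi = ranges$hi,
             pass = !is.na(value) & value >= ranges$lo & value <= ranges$hi,
             stringsAsFactors = FALSE, row.names = NULL)
}
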