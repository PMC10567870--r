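sheet_markers <- function(sample) {
  cols <- names(sample)
  sub("_rep1$", "", grep("_rep1$", cols, value = TRUE))
}

#' Quality-control check for one sample
#'
#' Applies the acceptance rules: the bisulfite conversion control must pass,
#' the DNA concentration must reach the minimum input for conversion
#' (2.5 ng/ul by default), and the two replicate measurements of each marker
#' may deviate by at most `deviation_bound` percentage points (5 by default).
#' The bound is read as absolute percentage points, not relative percent --- a
#' relative rule would reject any difference near 0% methylation.
#'
#' @param sample A one-row sample sheet (data frame row or named list) with
#'   `<marker>_rep1`/`_rep2` columns and optionally `conversion_control`
#'   ("pass"/"fail") and `concentration_ng_ul`.
#' @param deviation_bound Maximum allowed duplicate deviation, percentage
#'   points.
#' @param min_concentration Minimum DNA concentration, ng/ul.
#' @return A `qc_report` list: `sample_id`, `conversion_control_pass`,
#'   `concentration_ok`, `usable`, and `markers`, a tibble with one row per
#'   marker (`rep1`, `rep2`, `deviation`, `status` in
#'   pass/fail_deviation/missing).
#' @export
#' @examples
#' s <- list(sample_id = "case1", SA4_rep1 = 30, SA4_rep2 = 34,
#'           conversion_control = "pass", concentration_ng_ul = 5)
#' check_sample(s)
check_sample <- function(sample, deviation_bound = 5,
                         min_concentration = 2.5) {
  markers <- sheet_markers(sample)
  if (!length(markers)) stop("sample carries no replicate measurements")
  rep1 <- vapply(markers, function(m)
    as.numeric(sample[[paste0(m, "_rep1")]] %||% NA), numeric(1),
    USE.NAMES = FALSE)
  rep2 <- vapply(markers, function(m)
    as.numeric(sample[[paste0(m, "_rep2")]] %||% NA), numeric(1),
    USE.NAMES = FALSE)
  if (all(is.na(rep1)) && all(is.na(rep2))) {
    stop("sample carries no replicate measurements")
  }
  deviation <- abs(rep1 - rep2)
  status <- ifelse(is.na(rep1) | is.na(rep2), "missing",
                   ifelse(deviation > deviation_bound,
                          "fail_deviation", "pass"))
  conc <- as.numeric(sample[["concentration_ng_ul"]] %||% NA)
  conv <- sample[["conversion_control"]] %||% "pass"
  conv_pass <- identical(as.character(conv), "pass")
  conc_ok <- is.na(conc) || conc >= min_concentration
  structure(list(
    sample_id = as.character(sample[["sample_id"]] %||% "sample"),
    conversion_control_pass = conv_pass,
    concentration_ok = conc_ok,
    usable = conv_pass && conc_ok,
    markers = tibble::tibble(marker = markers, rep1 = rep1, rep2 = rep2,
                             deviation = deviation, status = status)
  ), class = "qc_report")
}

#' Collapse duplicate measurements to one value per marker
#'
#' Markers whose duplicates passed QC map to the arithmetic mean of the two
#' replicates; failing or missing markers are dropped, so downstream
#' classification sees a partial profile rather than an imputed value. A
#' failed conversion control (or, by default, an insufficient concentration)
#' makes the whole sample unusable: the collapsed map is empty.
#'
#' @param sample One-row sample sheet.
#' @param report QC report from [check_sample()]; recomputed when omitted.
#' @param allow_single Accept a marker with a single replicate, using that
#'   value. Off by default: the protocol measures everything in duplicate.
#' @param enforce Which sample-level gates empty the map:
#'   `"conversion"`, `"concentration"` or both (default).
#' @return Named numeric vector, marker -> collapsed methylation percentage.
#' @export
#' @examples
#' s <- list(SA4_rep1 = 30, SA4_rep2 = 34, V2_rep1 = 10, V2_rep2 = 21)
#' collapse_replicates(s)  # SA4 = 32; V2 dropped (deviation 11 > 5)
collapse_replicates <- function(sample, report = NULL, allow_single = FALSE,
                                enforce = c("conversion", "concentration")) {
  if (is.null(report)) report <- check_sample(sample)
  if (("conversion" %in% enforce && !report$conversion_control_pass) ||
      ("concentration" %in% enforce && !report$concentration_ok)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  mk <- report$markers
  value <- (mk$rep1 + mk$rep2) / 2
  keep <- mk$status == "pass"
  if (allow_single) {
    single <- mk$status == "missing" & (!is.na(mk$rep1) | !is.na(mk$rep2))
    value[single] <- ifelse(is.na(mk$rep1[single]),
                            mk$rep2[single], mk$rep1[single])
    keep <- keep | single
  }
  stats::setNames(value[keep], mk$marker[keep])
}

#' QC report for a whole sample sheet
#'
#' @param sheet Sample-sheet tibble (see [generate_cohort()] /
#'   [read_sample_sheet()]).
#' @inheritParams check_sample
#' @param path Optional path: the per-marker table is written as
#'   tab-separated text.
#' @return A list with `per_marker` (tibble: sample_id, marker, rep1, rep2,
#'   deviation, status) and `per_sample` (tibble: sample_id,
#'   conversion_control_pass, concentration_ok, usable).
#' @export
qc_report <- function(sheet, deviation_bound = 5, min_concentration = 2.5,
                      path = NULL) {
  reports <- lapply(seq_len(nrow(sheet)), function(i)
    check_sample(sheet[i, ], deviation_bound, min_concentration))
  per_marker <- do.call(rbind, lapply(reports, function(r)
    cbind(tibble::tibble(sample_id = r$sample_id), r$markers)))
  per_sample <- tibble::tibble(
    sample_id = vapply(reports, `[[`, character(1), "sample_id"),
    conversion_control_pass =
      vapply(reports, `[[`, logical(1), "conversion_control_pass"),
    concentration_ok = vapply(reports, `[[`, logical(1), "concentration_ok"),
    usable = vapply(reports, `[[`, logical(1), "usable"))
  if (!is.null(path)) {
    utils::write.table(per_marker, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(per_marker = tibble::as_tibble(per_marker), per_sample = per_sample)
}

#' Collapse a whole sheet to long-format analyzable values
#'
#' Runs [check_sample()] and [collapse_replicates()] on every row.
#'
#' @inheritParams qc_report
#' @inheritParams collapse_replicates
#' @return Long tibble: `sample_id`, `true_composition` (if present in the
#'   sheet), `marker`, `value`.
#' @export
collapse_cohort <- function(sheet, deviation_bound = 5,
                            min_concentration = 2.5, allow_single = FALSE,
                            enforce = c("conversion", "concentration")) {
  rows <- lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet[i, ]
    rep <- check_sample(s, deviation_bound, min_concentration)
    prof <- collapse_replicates(s, rep, allow_single, enforce)
    if (!length(prof)) return(NULL)
    out <- tibble::tibble(sample_id = rep$sample_id,
                          marker = names(prof), value = unname(prof))
    if (!is.null(s[["true_composition"]])) {
      out <- cbind(out[, "sample_id", drop = FALSE],
                   tibble::tibble(true_composition = s[["true_composition"]]),
                   out[, c("marker", "value")])
    }
    out
  })
  tibble::as_tibble(do.call(rbind, rows))
}
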