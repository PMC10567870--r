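#' Fluids excluded by negative pre-tests
#'
#' A negative hemoglobin test excludes all blood-containing fluids
#' (peripheral, menstrual and nasal blood); negative amylase excludes saliva;
#' a negative seminal test excludes sperm secretion. `not_done` excludes
#' nothing.
#'
#' @param pretests A [pretest_panel()].
#' @return Named character vector: excluded fluid -> reason.
#' @export
#' @examples
#' exclude_by_pretests(pretest_panel("negative", "negative", "negative"))
exclude_by_pretests <- function(pretests) {
  pretests <- as_pretest_panel(pretests)
  out <- character(0)
  if (pretests[["blood"]] == "negative") {
    out <- c(out, stats::setNames(
      rep("negative blood pre-test", 3),
      c("peripheral_blood", "menstrual_blood", "nasal_blood")))
  }
  if (pretests[["saliva"]] == "negative") {
    out <- c(out, stats::setNames("negative saliva pre-test", "saliva"))
  }
  if (pretests[["sperm"]] == "negative") {
    out <- c(out, stats::setNames("negative sperm pre-test",
                                  "sperm_secretion"))
  }
  out
}

#' Select the methylation markers to analyze for a stain
#'
#' Mirrors the marker-selection logic of the decision workflow: the blood
#' panel (NB21, B7, MB4) is run only when the hemoglobin test was positive
#' (or not done), to resolve which blood-containing fluid is present; SA4 is
#' run unless the amylase test already excluded saliva; V2 is run unless
#' blood is confirmed present, in which case it cannot separate vaginal
#' secretion from menstrual blood; N27SE is always run, as the only marker
#' for nasal samples (no pre-test exists) and the confirmatory marker for
#' sperm.
#'
#' @param pretests A [pretest_panel()].
#' @return Character vector of marker names, in panel order.
#' @export
#' @examples
#' select_markers(pretest_panel("negative", "negative", "negative"))  # V2, N27SE
select_markers <- function(pretests) {
  pretests <- as_pretest_panel(pretests)
  keep <- c(
    NB21 = pretests[["blood"]] != "negative",
    B7 = pretests[["blood"]] != "negative",
    MB4 = pretests[["blood"]] != "negative",
    SA4 = pretests[["saliva"]] != "negative",
    V2 = pretests[["blood"]] != "positive",
    N27SE = TRUE)
  MF_MARKERS[keep[MF_MARKERS]]
}

# Resolve a nasal-pair outcome to a concrete label using the blood pre-test;
# NB21 (and the N27SE nasal band) cannot separate nasal secretion from nasal
# blood on their own.
nasal_pair_label <- function(pretests) {
  switch(pretests[["blood"]],
         positive = "nasal_blood",
         negative = "nasal_secretion",
         "nasal_secretion_or_nasal_blood")
}

#' Classify one collapsed methylation profile
#'
#' Applies the tiered-threshold decision procedure: pre-test exclusions
#' first, then the applicable threshold tiers per marker (most specific
#' first), then fluid components supported by a positive pre-test whose
#' methylation evidence does not contradict it. All comparisons are strict
#' and values are used at full precision. The function is deterministic.
#'
#' Calls are composed as follows. A *full* call means the fluid is clearly
#' identified; a *partial* call means the fluid is present at least as a
#' mixture component. A fluid excluded by a negative pre-test is never
#' called; a tier naming an excluded fluid is recorded as a conflict flag
#' instead. Vaginal-tract evidence (V2 > 25) resolves to vaginal secretion
#' when blood is excluded, otherwise to the composite
#' `vaginal_tract_secretion`. A positive sperm test with N27SE below the
#' sperm cutoff still reports sperm as a sub-component, unless N27SE sits
#' below the lowest value observed for sperm-containing mixtures (33%).
#'
#' @param profile Named numeric vector, marker -> collapsed methylation
#'   percentage (markers may be missing; QC-failed markers simply narrow the
#'   evidence).
#' @param pretests A [pretest_panel()].
#' @param rules Tier tibble, see [default_thresholds()].
#' @param sample_id Label carried into the result.
#' @return A `fluid_call` object: list with `sample_id`, `called` (all
#'   fluids/composites deemed present), `full`, `partial`, `mixture`,
#'   `undetermined`, `excluded` (named reasons), `evidence` (per-tier
#'   tibble), `flags`.
#' @export
#' @examples
#' classify(c(V2 = 8, N27SE = 29),
#'          pretest_panel("negative", "negative", "negative"))
classify <- function(profile, pretests, rules = default_thresholds(),
                     sample_id = "sample") {
  pretests <- as_pretest_panel(pretests)
  if (length(profile)) {
    if (is.null(names(profile))) stop("profile must be a named vector")
    if (any(is.na(profile) | profile < 0 | profile > 100)) {
      stop("methylation values must lie in [0, 100]")
    }
    missing_rules <- setdiff(names(profile), rules$marker)
    if (length(missing_rules)) {
      stop("marker(s) absent from threshold rules: ",
           paste(missing_rules, collapse = ", "))
    }
  }
  excluded <- exclude_by_pretests(pretests)
  flags <- character(0)

  markers <- intersect(MF_MARKERS, names(profile))
  evidence <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[i]
    tiers <- resolve_thresholds(mk, pretests, rules)
    if (!nrow(tiers)) next
    fired <- vapply(seq_len(nrow(tiers)), function(j)
      tier_fires(tiers[j, ], profile[[mk]]), logical(1))
    evidence[[i]] <- cbind(
      tibble::tibble(marker = mk, value = unname(profile[[mk]])),
      tiers[, c("tier", "comparator", "lower", "upper", "outcome", "call",
                "cond_blood", "cond_saliva", "cond_sperm")],
      tibble::tibble(fired = fired))
  }
  evidence <- if (length(markers)) {
    tibble::as_tibble(do.call(rbind, evidence))
  } else {
    tibble::tibble(marker = character(0), value = numeric(0))
  }

  full <- character(0)
  partial <- character(0)
  mixture_band <- FALSE

  add_call <- function(fluid, type) {
    if (fluid %in% names(excluded)) {
      flags <<- c(flags, sprintf(
        "threshold evidence for %s ignored (%s)", fluid, excluded[[fluid]]))
      return(invisible(NULL))
    }
    if (type == "full") {
      full <<- union(full, fluid)
      partial <<- setdiff(partial, fluid)
    } else if (!fluid %in% full) {
      partial <<- union(partial, fluid)
    }
    invisible(NULL)
  }

  fired_rows <- if (nrow(evidence)) {
    evidence[evidence$fired, , drop = FALSE]
  } else {
    evidence
  }
  # full and mixture calls first, so later partial evidence cannot demote them
  fired_rows <- fired_rows[order(match(fired_rows$call,
                                       c("mixture", "full", "partial"))), ,
                           drop = FALSE]
  for (j in seq_len(nrow(fired_rows))) {
    row <- fired_rows[j, ]
    type <- if (row$call == "mixture") "full" else row$call
    switch(row$outcome,
      nasal_pair = add_call(nasal_pair_label(pretests), type),
      peripheral_blood = add_call("peripheral_blood", type),
      menstrual_blood = add_call("menstrual_blood", type),
      menstrual_sperm_mixture = {
        add_call("menstrual_blood", "full")
        add_call("sperm_secretion", "full")
        mixture_band <- TRUE
      },
      saliva = add_call("saliva", type),
      vaginal_secretion = add_call("vaginal_secretion", type),
      vaginal_tract = {
        if (pretests[["blood"]] == "negative") {
          add_call("vaginal_secretion", "partial")
        } else if (!"vaginal_secretion" %in% full) {
          add_call("vaginal_tract_secretion", "partial")
        }
      },
      sperm_secretion = add_call("sperm_secretion", type))
  }

  # components supported by a positive pre-test, unless contradicted
  called_so_far <- function() c(full, partial)
  if (pretests[["sperm"]] == "positive" &&
      !"sperm_secretion" %in% called_so_far()) {
    contradicted <- "N27SE" %in% names(profile) && profile[["N27SE"]] < 33
    if (!contradicted) {
      add_call("sperm_secretion", "partial")
      flags <- c(flags,
                 "sperm secretion supported by positive pre-test")
    } else {
      flags <- c(flags,
        "positive sperm pre-test not supported by N27SE methylation")
    }
  }
  if (pretests[["saliva"]] == "positive" && !"saliva" %in% called_so_far()) {
    contradicted <- "SA4" %in% names(profile) && !(profile[["SA4"]] > 18)
    if (!contradicted) {
      add_call("saliva", "partial")
      flags <- c(flags, "saliva supported by positive pre-test")
    } else {
      flags <- c(flags,
        "positive saliva pre-test not supported by SA4 methylation")
    }
  }
  if (pretests[["blood"]] == "positive") {
    bloods <- c("peripheral_blood", "menstrual_blood", "nasal_blood",
                "nasal_secretion_or_nasal_blood", "blood_unspecified")
    if (!any(bloods %in% called_so_far())) {
      add_call("blood_unspecified", "partial")
      flags <- c(flags, paste(
        "positive blood pre-test: a blood-containing fluid is present",
        "but the methylation profile does not resolve which"))
    }
  }

  # menstrual blood vs peripheral blood + vaginal secretion is not separable
  if (pretests[["blood"]] == "positive" &&
      "B7" %in% names(profile) && "V2" %in% names(profile) &&
      profile[["B7"]] > 18 && profile[["B7"]] <= 80 &&
      profile[["V2"]] > 25) {
    flags <- c(flags, paste(
      "menstrual blood cannot be distinguished from a mixture of",
      "peripheral blood and vaginal secretion"))
  }

  missing_markers <- setdiff(MF_MARKERS, names(profile))
  if (length(missing_markers)) {
    flags <- c(flags, paste0("markers not analyzed: ",
                             paste(missing_markers, collapse = ", ")))
  }

  called <- c(full, setdiff(partial, full))
  structure(list(
    sample_id = sample_id,
    called = called,
    full = full,
    partial = partial,
    mixture = mixture_band || length(called) > 1,
    undetermined = length(called) == 0,
    excluded = excluded,
    evidence = evidence,
    flags = flags
  ), class = "fluid_call")
}

#' @export
format.fluid_call <- function(x, ...) {
  lines <- c(sprintf("Sample %s", x$sample_id))
  if (length(x$excluded)) {
    lines <- c(lines, sprintf("  Excluded by pre-tests: %s",
                              paste(names(x$excluded), collapse = ", ")))
  }
  if (nrow(x$evidence)) {
    fired <- x$evidence[x$evidence$fired, ]
    for (mk in unique(x$evidence$marker)) {
      v <- x$evidence$value[x$evidence$marker == mk][1]
      hit <- fired[fired$marker == mk, ]
      msg <- if (nrow(hit)) {
        paste(unique(sprintf("%s (%s)", hit$outcome, hit$call)),
              collapse = "; ")
      } else "no tier fired"
      lines <- c(lines, sprintf("  %s = %.4g%%: %s", mk, v, msg))
    }
  }
  verdict <- if (x$undetermined) {
    "  Verdict: undetermined (no fluid identified)"
  } else {
    sprintf("  Verdict: %s%s",
            paste(x$called, collapse = " + "),
            if (x$mixture) " (mixture)" else "")
  }
  lines <- c(lines, verdict)
  if (length(x$flags)) {
    lines <- c(lines, sprintf("  Note: %s", x$flags))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.fluid_call <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Classify every sample of a sheet
#'
#' Runs QC, collapses duplicates, reads the pre-test columns and classifies
#' each sample. Samples that fail sample-level QC (conversion control or
#' concentration) come back undetermined with an explanatory flag.
#'
#' @param sheet Sample-sheet tibble (see [read_sample_sheet()]).
#' @param rules Tier tibble.
#' @param deviation_bound,min_concentration,allow_single QC settings, see
#'   [check_sample()] / [collapse_replicates()].
#' @param narratives_path Optional path: per-sample narrative reports are
#'   written there as plain text.
#' @return Tibble: `sample_id`, `called_fluids` (semicolon-joined),
#'   `partial_components`, `mixture`, `undetermined`, `n_markers_used`,
#'   `flags`; the full `fluid_call` objects are in `attr(, "results")`.
#' @export
classify_sheet <- function(sheet, rules = default_thresholds(),
                           deviation_bound = 5, min_concentration = 2.5,
                           allow_single = FALSE, narratives_path = NULL) {
  results <- lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet[i, ]
    pt <- pretest_panel(
      blood = as.character(s[["pretest_blood"]] %||% "not_done"),
      saliva = as.character(s[["pretest_saliva"]] %||% "not_done"),
      sperm = as.character(s[["pretest_sperm"]] %||% "not_done"))
    rep <- check_sample(s, deviation_bound, min_concentration)
    prof <- collapse_replicates(s, rep, allow_single)
    res <- classify(prof, pt, rules, sample_id = rep$sample_id)
    if (!rep$usable) {
      res$flags <- c(res$flags, "sample failed QC gates; no value usable")
    }
    res
  })
  out <- tibble::tibble(
    sample_id = vapply(results, `[[`, character(1), "sample_id"),
    called_fluids = vapply(results, function(r)
      paste(r$called, collapse = ";"), character(1)),
    partial_components = vapply(results, function(r)
      paste(r$partial, collapse = ";"), character(1)),
    mixture = vapply(results, `[[`, logical(1), "mixture"),
    undetermined = vapply(results, `[[`, logical(1), "undetermined"),
    n_markers_used = vapply(results, function(r)
      length(unique(r$evidence$marker)), integer(1)),
    flags = vapply(results, function(r)
      paste(r$flags, collapse = " | "), character(1)))
  if (!is.null(narratives_path)) {
    writeLines(vapply(results, format, character(1)), narratives_path)
  }
  attr(out, "results") <- results
  out
}
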