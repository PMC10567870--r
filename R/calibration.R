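#' Summarize a labeled single-source cohort per (fluid, marker)
#'
#' Computes the reference-table statistics (n, mean, SD, min, max) from
#' collapsed, labeled profiles. Input must be single-source: a mixture label
#' is an error, because mixture values are not draws from any one fluid's
#' distribution.
#'
#' @param profiles Long tibble with columns `fluid` (or `true_composition`
#'   with a single component), `marker`, `value`; e.g. the output of
#'   [collapse_cohort()] on a single-source cohort.
#' @return Tibble with columns `fluid`, `marker`, `n`, `mean`, `sd`, `min`,
#'   `max` (cells with no contributing samples are absent; `sd` is 0 for
#'   n = 1).
#' @export
summarize_cohort <- function(profiles) {
  if (!"fluid" %in% names(profiles)) {
    if (!"true_composition" %in% names(profiles)) {
      stop("profiles need a 'fluid' or 'true_composition' column")
    }
    comp <- profiles$true_composition
    if (any(grepl(";", comp, fixed = TRUE))) {
      stop("mixture-labeled sample passed to summarize_cohort")
    }
    profiles$fluid <- sub(":.*$", "", comp)
  }
  if (!all(c("marker", "value") %in% names(profiles))) {
    stop("profiles need 'marker' and 'value' columns")
  }
  key <- interaction(profiles$fluid, profiles$marker, drop = TRUE)
  rows <- lapply(split(profiles, key), function(df) {
    tibble::tibble(fluid = df$fluid[1], marker = df$marker[1],
                   n = nrow(df), mean = mean(df$value),
                   sd = if (nrow(df) > 1) stats::sd(df$value) else 0,
                   min = min(df$value), max = max(df$value))
  })
  out <- do.call(rbind, rows)
  out[order(match(out$marker, MF_MARKERS), out$fluid), ]
}

#' Derive a marker cutoff from target and non-target values
#'
#' Places the cutoff at the edge of the non-target range, the way the
#' published thresholds were set: for a below-direction marker the cutoff is
#' `floor(min(non-target)) - 1 - margin` and the call fires for values
#' strictly below it; for an above-direction marker it is
#' `ceil(max(non-target)) + margin`, firing strictly above. All published
#' cutoffs are integers; the derivation preserves that. The published panel
#' itself used heterogeneous margins (0 for B7, effectively 0 for NB21 via
#' the floor-minus-one rule, 4 for MB4), so the margin is explicit data, not
#' something this function guesses.
#'
#' When the target and non-target ranges overlap, a warning reports the
#' fraction of target values on the wrong side of the non-target extreme
#' (those can never be called at any margin >= 0).
#'
#' @param target_values Methylation percentages of the target fluid (may be
#'   empty; used only for the overlap warning).
#' @param nontarget_values Non-target methylation percentages (non-empty).
#' @param direction `"below"` or `"above"`: the side on which the target
#'   sits.
#' @param margin Extra safety margin in percentage points.
#' @return The cutoff (numeric scalar).
#' @export
#' @examples
#' derive_cutoff(numeric(0), c(68, 100), "below")   # 67
#' derive_cutoff(numeric(0), c(2, 80), "above")     # 80
#' derive_cutoff(numeric(0), c(1, 17), "above", margin = 4)  # 21
derive_cutoff <- function(target_values, nontarget_values,
                          direction = c("below", "above"), margin = 0) {
  direction <- match.arg(direction)
  if (!length(nontarget_values)) stop("non-target values must be non-empty")
  cutoff <- if (direction == "below") {
    floor(min(nontarget_values)) - 1 - margin
  } else {
    ceiling(max(nontarget_values)) + margin
  }
  if (length(target_values)) {
    wrong <- if (direction == "below") {
      target_values >= min(nontarget_values)
    } else {
      target_values <= max(nontarget_values)
    }
    if (any(wrong)) {
      warning(sprintf(
        "target and non-target ranges overlap: %.1f%% of target values cannot be separated",
        100 * mean(wrong)))
    }
  }
  cutoff
}

#' Derive cutoffs for the whole panel from a cohort summary
#'
#' Re-derives each marker's base cutoff by pooling all non-target fluids'
#' values (approximated from each cell's min/max range endpoints), the
#' procedure used to set the published thresholds. Conditional cutoffs are
#' obtained by dropping the pre-test-excluded fluids from the non-target
#' pool via `exclude`.
#'
#' @param summary Output of [summarize_cohort()].
#' @param marker Marker short name.
#' @param margin See [derive_cutoff()].
#' @param exclude Fluids removed from the non-target pool (e.g. those ruled
#'   out by a negative pre-test before the threshold applies).
#' @return Cutoff value.
#' @export
derive_marker_cutoff <- function(summary, marker, margin = 0,
                                 exclude = character(0)) {
  pm <- marker_panel()
  targets <- fluid_group(pm$targets[[match(marker, pm$marker)]])
  sub <- summary[summary$marker == marker, ]
  sub$grp <- fluid_group(sub$fluid)
  tgt <- sub[sub$grp %in% targets, ]
  non <- sub[!sub$grp %in% targets & !sub$grp %in% fluid_group(exclude), ]
  if (!nrow(non)) stop("no non-target fluids left for marker ", marker)
  direction <- if (pm$call_direction[match(marker, pm$marker)] ==
                   "below_cutoff") "below" else "above"
  derive_cutoff(c(tgt$min, tgt$max), c(non$min, non$max), direction, margin)
}

#' Human-readable calibration report
#'
#' @param summary Output of [summarize_cohort()].
#' @param path Optional path for the tab-separated per-marker range table.
#' @return The summary with ranges formatted, invisibly when written.
#' @export
calibration_report <- function(summary, path = NULL) {
  out <- summary
  out$range <- sprintf("%.2f-%.2f", out$min, out$max)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
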