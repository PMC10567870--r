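# Which tier outcomes count as an identification of each scoring target.
# (menstrual_sperm_mixture identifies menstrual blood on the MB4 block.)
outcome_hits_target <- function(outcome, call, target) {
  switch(target,
    nasal = outcome == "nasal_pair" & call != "partial",
    peripheral_blood = outcome == "peripheral_blood" & call != "partial",
    menstrual_blood =
      outcome %in% c("menstrual_blood", "menstrual_sperm_mixture"),
    saliva = outcome == "saliva" & call == "full",
    vaginal_secretion = outcome == "vaginal_secretion" & call == "full",
    sperm_secretion = outcome == "sperm_secretion" & call != "partial",
    stop("unknown scoring target: ", target))
}

marker_score_targets <- function(marker) {
  switch(marker,
         NB21 = "nasal",
         B7 = "peripheral_blood",
         MB4 = "menstrual_blood",
         SA4 = "saliva",
         V2 = "vaginal_secretion",
         N27SE = c("nasal", "sperm_secretion"),
         stop("unknown marker: ", marker))
}

#' Confusion counts for one marker rule
#'
#' Scores fired/not-fired results against truth labels for one target fluid.
#' Percentages are counts over the respective cohort, rounded half-up to two
#' decimals. Sensitivity on an empty target cohort (and specificity on an
#' empty non-target cohort) is reported as `NA` (not applicable), not 0.
#'
#' @param truth Character vector of truth labels.
#' @param fired Logical vector: did the marker's identifying rule fire?
#' @param target The truth label counted as target.
#' @return One-row tibble: `target`, `n`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`.
#' @export
#' @examples
#' score_marker(rep(c("nasal", "blood"), c(23, 22)),
#'              rep(c(TRUE, FALSE, FALSE), c(14, 9, 22)), "nasal")
score_marker <- function(truth, fired, target) {
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(fired)) stop("truth/fired length mismatch")
  is_t <- truth == target
  tp <- sum(is_t & fired)
  fn <- sum(is_t & !fired)
  fp <- sum(!is_t & fired)
  tn <- sum(!is_t & !fired)
  tibble::tibble(
    target = target, n = length(truth), tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) round_half_up(100 * tp / (tp + fn))
                  else NA_real_,
    specificity = if (tn + fp > 0) round_half_up(100 * tn / (tn + fp))
                  else NA_real_)
}

truth_group <- function(composition) {
  single <- !grepl(";", composition, fixed = TRUE)
  fluid <- sub(":.*$", "", composition)
  ifelse(single, fluid_group(fluid), NA_character_)
}

#' Per-marker validation report on a labeled cohort
#'
#' Classifies every single-source sample marker by marker and tabulates, for
#' each (marker, target, truth-fluid) cell, the cohort size and how often the
#' marker's identifying rule fired --- the layout of a validation confusion
#' table. N27SE is scored twice (nasal and sperm targets); for each of its
#' target rows the other target's cohort is left out, since the marker is
#' expected to fire there for the other reason. Mixture-labeled samples are
#' skipped with a warning.
#'
#' @param sheet Labeled sample sheet (needs `true_composition`).
#' @param rules Tier tibble.
#' @param deviation_bound,min_concentration QC settings.
#' @return Long tibble: `marker`, `target`, `truth`, `n`, `fired`.
#' @seealso [confusion_summary()] to reduce it to sensitivity/specificity.
#' @export
validation_report <- function(sheet, rules = default_thresholds(),
                              deviation_bound = 5, min_concentration = 2.5) {
  long <- collapse_cohort(sheet, deviation_bound, min_concentration)
  if (!"true_composition" %in% names(long)) {
    stop("sheet must carry a true_composition column")
  }
  long$truth <- truth_group(long$true_composition)
  mixed <- is.na(long$truth)
  if (any(mixed)) {
    warning(sprintf("skipping %d mixture-labeled measurement(s)",
                    sum(mixed)))
    long <- long[!mixed, ]
  }
  pt_cols <- sheet[match(long$sample_id, sheet$sample_id),
                   c("pretest_blood", "pretest_saliva", "pretest_sperm")]
  absent <- setdiff(MF_MARKERS, unique(long$marker))
  if (length(absent)) {
    warning("no usable measurements for marker(s): ",
            paste(absent, collapse = ", "), "; block(s) omitted")
  }
  rows <- list()
  for (mk in intersect(MF_MARKERS, unique(long$marker))) {
    sub <- long[long$marker == mk, ]
    pts <- pt_cols[long$marker == mk, ]
    fired_target <- function(target) {
      vapply(seq_len(nrow(sub)), function(i) {
        tiers <- resolve_thresholds(mk, pretest_panel(
          blood = pts$pretest_blood[i], saliva = pts$pretest_saliva[i],
          sperm = pts$pretest_sperm[i]), rules)
        if (!nrow(tiers)) return(FALSE)
        hit <- outcome_hits_target(tiers$outcome, tiers$call, target)
        any(hit & vapply(seq_len(nrow(tiers)), function(j)
          tier_fires(tiers[j, ], sub$value[i]), logical(1)))
      }, logical(1))
    }
    for (target in marker_score_targets(mk)) {
      drop <- setdiff(marker_score_targets(mk), target)
      keep <- !sub$truth %in% drop
      f <- fired_target(target)[keep]
      tr <- sub$truth[keep]
      for (g in unique(tr)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          marker = mk, target = target, truth = g,
          n = sum(tr == g), fired = sum(f[tr == g]))
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$marker, MF_MARKERS), out$target, out$truth), ]
}

#' Reduce a validation count table to sensitivity/specificity per rule
#'
#' Counts are conserved: per (marker, target) block,
#' tp + fp + tn + fn equals the number of scored samples, and the
#' percentages recompute exactly from the counts (two decimals, half-up).
#'
#' @param counts Long count table as produced by [validation_report()] (or
#'   read from a printed confusion table): columns `marker`, `target`,
#'   `truth`, `n`, `fired`.
#' @return Tibble, one row per (marker, target): counts and percentages.
#' @export
confusion_summary <- function(counts) {
  key <- interaction(counts$marker, counts$target, drop = TRUE)
  rows <- lapply(split(counts, key), function(df) {
    truth <- rep(df$truth, df$n)
    fired <- unlist(lapply(seq_len(nrow(df)), function(i)
      rep(c(TRUE, FALSE), c(df$fired[i], df$n[i] - df$fired[i]))))
    cbind(tibble::tibble(marker = df$marker[1]),
          score_marker(truth, fired, df$target[1]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$marker, MF_MARKERS), out$target), ]
  tibble::as_tibble(out)
}

#' Published validation counts
#'
#' The printed validation-study confusion counts shipped as a plain-text
#' fixture. For the V2/vaginal cell the printed table and the running text
#' disagree (10/10 vs 9/10 true positives); `source` selects which variant
#' to use, rows common to both are tagged `both`.
#'
#' @param source `"prose"` or `"table2"`.
#' @return Count table usable with [confusion_summary()].
#' @export
published_validation_counts <- function(source = c("prose", "table2")) {
  source <- match.arg(source)
  path <- system.file("extdata", "validation_counts.tsv",
                      package = "methylfluid", mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.delim(path,
                                             stringsAsFactors = FALSE))
  tab <- tab[tab$source %in% c("both", source), ]
  tab[, c("marker", "target", "truth", "n", "fired")]
}

#' Box-plot style per-marker summaries
#'
#' Quartile summaries of a labeled cohort per (fluid, marker), the numeric
#' content of per-marker box plots.
#'
#' @param profiles Long labeled profile tibble (see [summarize_cohort()]).
#' @return Tibble with quartiles and whisker values per cell.
#' @export
marker_quartiles <- function(profiles) {
  if (!"fluid" %in% names(profiles)) {
    profiles$fluid <- truth_group(profiles$true_composition)
  }
  key <- interaction(profiles$fluid, profiles$marker, drop = TRUE)
  rows <- lapply(split(profiles, key), function(df) {
    q <- stats::quantile(df$value, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    tibble::tibble(fluid = df$fluid[1], marker = df$marker[1], n = nrow(df),
                   min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                   max = q[5])
  })
  out <- do.call(rbind, rows)
  out[order(match(out$marker, MF_MARKERS), out$fluid), ]
}
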