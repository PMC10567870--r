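MF_OUTCOMES <- c("nasal_pair", "peripheral_blood", "menstrual_blood",
                 "menstrual_sperm_mixture", "saliva", "vaginal_secretion",
                 "vaginal_tract", "sperm_secretion")
MF_CALL_TYPES <- c("full", "partial", "mixture")
MF_COMPARATORS <- c("gt", "lt", "between")

new_tier <- function(marker, tier, comparator, lower, upper, outcome, call,
                     blood = NA_character_, saliva = NA_character_,
                     sperm = NA_character_, priority) {
  tibble::tibble(marker = marker, tier = tier, comparator = comparator,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 outcome = outcome, call = call,
                 cond_blood = blood, cond_saliva = saliva, cond_sperm = sperm,
                 priority = as.integer(priority))
}

#' Published default threshold rules
#'
#' The tiered threshold table of the established workflow. All comparisons are
#' strict: a methylation value exactly equal to a cutoff does not fire the
#' rule. Tiers carrying a pre-test condition (`cond_*` columns) are applicable
#' only when that rapid test returned exactly the required state; `not_done`
#' never satisfies a condition.
#'
#' Tiers, by marker:
#' * NB21: `< 67` identifies the nasal pair (nasal secretion or nasal blood).
#' * B7: `> 80` identifies pure peripheral blood.
#' * MB4: `> 21` menstrual blood unconditionally; `> 18` given a negative
#'   sperm pre-test; `18--21` with a positive sperm pre-test flags a
#'   menstrual blood + sperm secretion mixture.
#' * SA4: `> 35` saliva; `> 18` saliva as a partial mixture component.
#' * V2: `> 50` vaginal secretion unconditionally; `> 40` given a negative
#'   saliva pre-test; `> 25` proves vaginal-tract secretions (vaginal
#'   secretion or menstrual blood) without separating them.
#' * N27SE: `> 75` sperm secretion; a nasal band with fixed upper bound 70
#'   whose lower bound relaxes as pre-tests are confirmed negative:
#'   40 (sperm negative), 30 (sperm and blood negative), 22 (sperm, blood
#'   and saliva negative).
#'
#' @return A tibble of tiers with columns `marker`, `tier`, `comparator`
#'   (`gt`/`lt`/`between`), `lower`, `upper`, `outcome`, `call`
#'   (`full`/`partial`/`mixture`), `cond_blood`, `cond_saliva`, `cond_sperm`,
#'   `priority`, `n_conditions`.
#' @seealso [load_panel()], [resolve_thresholds()]
#' @export
default_thresholds <- function() {
  rules <- rbind(
    new_tier("NB21", "nasal_pair", "lt", NA, 67, "nasal_pair", "full",
             priority = 1),
    new_tier("B7", "peripheral_blood", "gt", 80, NA, "peripheral_blood",
             "full", priority = 1),
    new_tier("MB4", "menstrual", "gt", 21, NA, "menstrual_blood", "full",
             priority = 1),
    new_tier("MB4", "menstrual_sperm_neg", "gt", 18, NA, "menstrual_blood",
             "full", sperm = "negative", priority = 2),
    new_tier("MB4", "menstrual_sperm_mix", "between", 18, 21,
             "menstrual_sperm_mixture", "mixture", sperm = "positive",
             priority = 3),
    new_tier("SA4", "saliva", "gt", 35, NA, "saliva", "full", priority = 1),
    new_tier("SA4", "saliva_partial", "gt", 18, NA, "saliva", "partial",
             priority = 2),
    new_tier("V2", "vaginal", "gt", 50, NA, "vaginal_secretion", "full",
             priority = 1),
    new_tier("V2", "vaginal_saliva_neg", "gt", 40, NA, "vaginal_secretion",
             "full", saliva = "negative", priority = 2),
    new_tier("V2", "vaginal_tract", "gt", 25, NA, "vaginal_tract", "partial",
             priority = 3),
    new_tier("N27SE", "sperm", "gt", 75, NA, "sperm_secretion", "full",
             priority = 1),
    new_tier("N27SE", "nasal_band", "between", 40, 70, "nasal_pair", "full",
             sperm = "negative", priority = 2),
    new_tier("N27SE", "nasal_band_blood_neg", "between", 30, 70, "nasal_pair",
             "full", blood = "negative", sperm = "negative", priority = 3),
    new_tier("N27SE", "nasal_band_all_neg", "between", 22, 70, "nasal_pair",
             "full", blood = "negative", saliva = "negative",
             sperm = "negative", priority = 4)
  )
  finalize_rules(rules)
}

finalize_rules <- function(rules) {
  rules$n_conditions <- rowSums(!is.na(
    rules[, c("cond_blood", "cond_saliva", "cond_sperm")]))
  validate_rules(rules)
  rules
}

validate_rules <- function(rules) {
  known <- marker_panel()$marker
  bad <- setdiff(unique(rules$marker), known)
  if (length(bad)) {
    stop("unknown marker name(s) in threshold rules: ",
         paste(bad, collapse = ", "))
  }
  if (!all(rules$comparator %in% MF_COMPARATORS)) {
    stop("comparator must be one of ", paste(MF_COMPARATORS, collapse = ", "))
  }
  if (!all(rules$outcome %in% MF_OUTCOMES)) {
    stop("unknown outcome label(s): ",
         paste(setdiff(rules$outcome, MF_OUTCOMES), collapse = ", "))
  }
  if (!all(rules$call %in% MF_CALL_TYPES)) stop("invalid call type")
  bounds <- c(rules$lower, rules$upper)
  if (any(!is.na(bounds) & (bounds < 0 | bounds > 100))) {
    stop("threshold bound outside [0, 100]")
  }
  need_lower <- rules$comparator %in% c("gt", "between")
  need_upper <- rules$comparator %in% c("lt", "between")
  if (any(need_lower & is.na(rules$lower)) ||
      any(need_upper & is.na(rules$upper))) {
    stop("missing bound for comparator")
  }
  band <- rules$comparator == "between"
  if (any(band & rules$lower >= rules$upper)) {
    stop("band with lower bound >= upper bound")
  }
  conds <- c(rules$cond_blood, rules$cond_saliva, rules$cond_sperm)
  if (any(!is.na(conds) & !conds %in% c("positive", "negative"))) {
    stop("tier conditions must be 'positive' or 'negative'")
  }
  invisible(rules)
}

#' Load the marker panel and threshold rules
#'
#' With no configuration the published default rules are returned, so the
#' workflow runs with zero external files. A configuration (YAML file path or
#' an already-parsed list) overrides the tier list of the markers it names;
#' unnamed markers keep their defaults. The config dialect mirrors the tier
#' structure:
#'
#' ```yaml
#' markers:
#'   SA4:
#'     tiers:
#'     - {comparator: gt, lower: 35, outcome: saliva, call: full}
#'     - {comparator: gt, lower: 18, outcome: saliva, call: partial}
#'   MB4:
#'     tiers:
#'     - {comparator: gt, lower: 21, outcome: menstrual_blood, call: full}
#'     - comparator: gt
#'       lower: 18
#'       outcome: menstrual_blood
#'       call: full
#'       when: {sperm: negative}
#' ```
#'
#' @param config `NULL` (defaults), a path to a YAML config, or a list with a
#'   `markers` element as above.
#' @return A list with elements `panel` (see [marker_panel()]) and `rules`
#'   (tier tibble as in [default_thresholds()]).
#' @export
#' @examples
#' p <- load_panel()
#' subset(p$rules, marker == "NB21")
load_panel <- function(config = NULL) {
  rules <- default_thresholds()
  if (!is.null(config)) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (!is.list(config) || is.null(config$markers)) {
      stop("config must contain a 'markers' section")
    }
    rules <- rules[, setdiff(names(rules), "n_conditions")]
    for (mk in names(config$markers)) {
      spec <- config$markers[[mk]]
      tiers <- spec$tiers
      if (is.null(tiers)) stop("config for marker ", mk, " has no tiers")
      rows <- lapply(seq_along(tiers), function(i) {
        tr <- tiers[[i]]
        when <- tr$when
        new_tier(mk,
                 tier = tr$tier %||% paste0(mk, "_tier", i),
                 comparator = tr$comparator %||% stop("tier without comparator"),
                 lower = tr$lower %||% NA,
                 upper = tr$upper %||% NA,
                 outcome = tr$outcome %||% stop("tier without outcome"),
                 call = tr$call %||% "full",
                 blood = when$blood %||% NA_character_,
                 saliva = when$saliva %||% NA_character_,
                 sperm = when$sperm %||% NA_character_,
                 priority = i)
      })
      rules <- rbind(rules[rules$marker != mk, ], do.call(rbind, rows))
    }
    rules <- rules[order(match(rules$marker, MF_MARKERS), rules$priority), ]
    rules <- finalize_rules(rules)
  }
  list(panel = marker_panel(), rules = rules)
}

#' Write threshold rules as a panel configuration file
#'
#' Serializes a tier table to the YAML dialect read by [load_panel()].
#' Round-trips exactly: reloading the written file reproduces the same rules.
#'
#' @param rules Tier tibble (as produced by [default_thresholds()] or
#'   `load_panel()$rules`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(rules, path) {
  validate_rules(finalize_rules(rules[, setdiff(names(rules), "n_conditions")]))
  markers <- lapply(split(rules, factor(rules$marker, levels = MF_MARKERS)),
                    function(df) {
    df <- df[order(df$priority), ]
    tiers <- lapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      tr <- list(tier = r$tier, comparator = r$comparator)
      if (!is.na(r$lower)) tr$lower <- r$lower
      if (!is.na(r$upper)) tr$upper <- r$upper
      tr$outcome <- r$outcome
      tr$call <- r$call
      when <- list()
      if (!is.na(r$cond_blood)) when$blood <- r$cond_blood
      if (!is.na(r$cond_saliva)) when$saliva <- r$cond_saliva
      if (!is.na(r$cond_sperm)) when$sperm <- r$cond_sperm
      if (length(when)) tr$when <- when
      tr
    })
    list(tiers = tiers)
  })
  markers <- markers[!vapply(markers, function(m) length(m$tiers) == 0,
                             logical(1))]
  yaml::write_yaml(list(markers = markers), path)
  invisible(path)
}

#' Export the panel and tiers as a flat report table
#'
#' @param panel Output of [load_panel()].
#' @param path Optional path; when given, written as tab-separated text.
#' @return A tibble (one row per tier, joined with the marker's CpG id and
#'   target fluids), invisibly when `path` is given.
#' @export
panel_table <- function(panel = load_panel(), path = NULL) {
  pm <- panel$panel
  tab <- panel$rules
  tab$cpg_id <- pm$cpg_id[match(tab$marker, pm$marker)]
  tab$targets <- vapply(pm$targets[match(tab$marker, pm$marker)],
                        paste, character(1), collapse = ";")
  tab <- tab[, c("marker", "cpg_id", "targets", "tier", "comparator",
                 "lower", "upper", "outcome", "call",
                 "cond_blood", "cond_saliva", "cond_sperm")]
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

tier_applicable <- function(rules, pretests) {
  pretests <- as_pretest_panel(pretests)
  ok <- function(cond, state) is.na(cond) | cond == state
  ok(rules$cond_blood, pretests[["blood"]]) &
    ok(rules$cond_saliva, pretests[["saliva"]]) &
    ok(rules$cond_sperm, pretests[["sperm"]])
}

#' Resolve the applicable threshold tiers for a marker
#'
#' Filters a marker's tiers down to those whose pre-test conditions are
#' satisfied by the given rapid-test results, ordered most-specific first
#' (more conditions before fewer). A `not_done` pre-test satisfies no
#' condition, so conditional tiers stay inactive until the relevant test has
#' actually been run. Pure function: identical inputs give identical output.
#'
#' @param marker Marker short name (e.g. `"N27SE"`).
#' @param pretests A [pretest_panel()].
#' @param rules Tier tibble; defaults to the published rules.
#' @return Tibble of applicable tiers (possibly empty).
#' @export
#' @examples
#' resolve_thresholds("N27SE", pretest_panel(blood = "negative",
#'                                           sperm = "negative"))
resolve_thresholds <- function(marker, pretests,
                               rules = default_thresholds()) {
  if (!marker %in% marker_panel()$marker) {
    stop("unknown marker: ", marker)
  }
  sub <- rules[rules$marker == marker, ]
  sub <- sub[tier_applicable(sub, pretests), ]
  sub[order(-sub$n_conditions, sub$priority), ]
}

# Strict comparison of a methylation value against one tier.
tier_fires <- function(tier, value) {
  switch(tier$comparator,
         gt = value > tier$lower,
         lt = value < tier$upper,
         between = value > tier$lower & value < tier$upper)
}
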