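# Canonical orderings used throughout the package.
MF_MARKERS <- c("NB21", "B7", "MB4", "SA4", "V2", "N27SE")

MF_FLUIDS <- c("nasal_secretion", "nasal_blood", "peripheral_blood",
               "menstrual_blood", "saliva", "vaginal_secretion",
               "sperm_secretion")

# Composite outcome labels the classifier may emit when the evidence cannot
# separate members of a group.
MF_COMPOSITES <- c("nasal_secretion_or_nasal_blood",
                   "vaginal_tract_secretion",
                   "blood_unspecified")

MF_PRETEST_STATES <- c("positive", "negative", "not_done")

#' Body fluid taxonomy
#'
#' The seven secretions the workflow can identify, with the properties that
#' drive pre-test semantics: whether the fluid contains blood cells (and hence
#' triggers the hemoglobin rapid test) and which of the three rapid tests it
#' triggers.
#'
#' @return A tibble with columns `name`, `blood_containing`, `triggers_blood`,
#'   `triggers_saliva`, `triggers_sperm`.
#' @export
#' @examples
#' body_fluids()
body_fluids <- function() {
  tibble::tibble(
    name = MF_FLUIDS,
    blood_containing = MF_FLUIDS %in%
      c("nasal_blood", "peripheral_blood", "menstrual_blood"),
    triggers_blood = MF_FLUIDS %in%
      c("nasal_blood", "peripheral_blood", "menstrual_blood"),
    triggers_saliva = MF_FLUIDS == "saliva",
    triggers_sperm = MF_FLUIDS == "sperm_secretion"
  )
}

#' CpG marker panel
#'
#' The six retained CpG markers, their Illumina-style probe identifiers, the
#' fluids they target, and the direction in which a call fires. NB21 targets
#' the nasal pair (nasal secretion or nasal blood, which it cannot separate on
#' its own); N27SE targets both nasal samples and sperm secretion, at opposite
#' ends of its methylation range.
#'
#' @return A tibble with columns `marker`, `cpg_id`, `targets` (list column of
#'   fluid names), `call_direction`.
#' @export
marker_panel <- function() {
  tibble::tibble(
    marker = MF_MARKERS,
    cpg_id = c("cg16518142", "cg13763232", "cg04255276",
               "cg21597595", "cg26079753", "cg20864568"),
    targets = list(
      c("nasal_secretion", "nasal_blood"),
      "peripheral_blood",
      "menstrual_blood",
      "saliva",
      "vaginal_secretion",
      c("nasal_secretion", "sperm_secretion")
    ),
    call_direction = c("below_cutoff", "above_cutoff", "above_cutoff",
                       "above_cutoff", "above_cutoff", "band")
  )
}

#' Rapid pre-test panel
#'
#' Result of the three stain rapid tests (hemoglobin for blood, amylase for
#' saliva, seminal markers for sperm). `not_done` is uninformative: it neither
#' excludes a fluid nor activates threshold tiers that require a confirmed
#' negative.
#'
#' @param blood,saliva,sperm One of `"positive"`, `"negative"`, `"not_done"`.
#' @return A named character vector of class `pretest_panel`.
#' @export
#' @examples
#' pretest_panel(blood = "positive", sperm = "positive", saliva = "negative")
pretest_panel <- function(blood = "not_done", saliva = "not_done",
                          sperm = "not_done") {
  blood <- match.arg(blood, MF_PRETEST_STATES)
  saliva <- match.arg(saliva, MF_PRETEST_STATES)
  sperm <- match.arg(sperm, MF_PRETEST_STATES)
  structure(c(blood = blood, saliva = saliva, sperm = sperm),
            class = "pretest_panel")
}

as_pretest_panel <- function(x) {
  if (inherits(x, "pretest_panel")) return(x)
  if (is.null(names(x)) || !all(c("blood", "saliva", "sperm") %in% names(x))) {
    stop("pre-tests must be named with 'blood', 'saliva' and 'sperm'")
  }
  pretest_panel(blood = x[["blood"]], saliva = x[["saliva"]],
                sperm = x[["sperm"]])
}

# Map a fluid (or distribution-group) name onto the column grouping of the
# reference table: the two nasal fluids share one distribution group.
fluid_group <- function(fluid) {
  ifelse(fluid %in% c("nasal_secretion", "nasal_blood", "nasal"),
         "nasal", fluid)
}
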