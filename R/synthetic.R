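#' Reference methylation distributions per fluid and marker
#'
#' Per-(fluid group, marker) distribution parameters of the reference cohort:
#' sample size, mean and standard deviation of the methylation percentage,
#' plus a heavy-tail ("outlier") component for the three cells where the
#' reference data showed isolated values far outside the core range
#' (peripheral blood at B7: 7/42 samples down to 60%; sperm at N27SE: 2/18 at
#' 81% and 73%; nasal at N27SE: 1/52 at 8%). The two nasal fluids share one
#' group ("nasal"); the optional post-menopausal vaginal subpopulation
#' (V2 mean 22, SD 7) can be added as its own group.
#'
#' `mean` and `sd` describe the full observed sample *including* outliers;
#' the generator de-mixes the outlier component so that simulated cohorts
#' converge to these moments.
#'
#' @param include_postmenopausal Add a `vaginal_postmenopausal` group (V2
#'   shifted to mean 22, SD 7; other markers as for vaginal secretion).
#' @return Tibble with columns `group`, `marker`, `n_ref`, `mean`, `sd`,
#'   `outlier_rate`, `outlier_kind` (`NA`, `"uniform"`, `"points"`),
#'   `outlier_lower`, `outlier_upper`, `outlier_values` (list column).
#' @export
marker_distributions <- function(include_postmenopausal = FALSE) {
  groups <- c("nasal", "peripheral_blood", "menstrual_blood", "saliva",
              "vaginal_secretion", "sperm_secretion")
  d <- tibble::tibble(
    group = rep(groups, times = 6),
    marker = rep(MF_MARKERS, each = 6),
    n_ref = c(46, 44, 18, 46, 30, 19,     # NB21
              46, 42, 27, 44, 22, 18,     # B7
              44, 47, 23, 45, 24, 18,     # MB4
              45, 45, 18, 46, 18, 17,     # SA4
              45, 45, 18, 41, 22, 19,     # V2
              52, 46, 20, 42, 21, 18),    # N27SE
    mean = c(75.13, 89.93, 82.94, 91.96, 82.23, 98.21,
             37.65, 87.43, 41.37, 30.57, 30.91,  9.06,
              7.52,  9.47, 20.39,  7.76,  5.79,  5.00,
              7.49,  5.82,  5.22, 38.98,  6.89,  2.00,
              8.51, 12.60, 22.33, 11.32, 53.55,  8.89,
             31.40, 24.89, 23.65, 20.36, 14.62, 90.39),
    sd = c(17.55, 5.74, 7.44, 5.78, 7.50, 1.91,
           26.84, 7.11, 22.75, 16.42, 13.87, 7.77,
            4.49, 3.53, 11.84, 3.68, 3.11, 2.69,
            3.41, 4.27, 2.46, 10.91, 3.62, 1.28,
            3.19, 4.13, 9.30, 4.53, 13.35, 3.42,
            8.76, 3.97, 8.82, 5.80, 3.85, 5.31),
    outlier_rate = 0,
    outlier_kind = NA_character_,
    outlier_lower = NA_real_,
    outlier_upper = NA_real_,
    outlier_values = vector("list", 36)
  )
  set_outlier <- function(d, group, marker, rate, kind,
                          lower = NA, upper = NA, values = NULL) {
    i <- which(d$group == group & d$marker == marker)
    d$outlier_rate[i] <- rate
    d$outlier_kind[i] <- kind
    d$outlier_lower[i] <- lower
    d$outlier_upper[i] <- upper
    d$outlier_values[i] <- list(values)
    d
  }
  d <- set_outlier(d, "peripheral_blood", "B7", 7 / 42, "uniform",
                   lower = 60, upper = 87.43)
  d <- set_outlier(d, "sperm_secretion", "N27SE", 2 / 18, "points",
                   values = c(81, 73))
  d <- set_outlier(d, "nasal", "N27SE", 1 / 52, "points", values = 8)
  if (include_postmenopausal) {
    pm <- d[d$group == "vaginal_secretion", ]
    pm$group <- "vaginal_postmenopausal"
    pm$n_ref <- 4
    i <- which(pm$marker == "V2")
    pm$mean[i] <- 22
    pm$sd[i] <- 7
    d <- rbind(d, pm)
  }
  d
}

# Beta shape parameters matched to a mean/sd on the 0-100 scale. Methylation
# fractions are bounded in [0,1]; the beta family matches any feasible
# (mean, sd) pair exactly, which keeps large simulated cohorts centred on the
# configured reference moments.
beta_shapes <- function(mean, sd) {
  m <- mean / 100
  v <- (sd / 100)^2
  if (v >= m * (1 - m)) {
    stop(sprintf("sd %.2f infeasible for a bounded distribution with mean %.2f",
                 sd, mean))
  }
  k <- m * (1 - m) / v - 1
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

# Moments of the outlier component of one distribution row.
outlier_moments <- function(row) {
  if (row$outlier_kind == "uniform") {
    m <- (row$outlier_lower + row$outlier_upper) / 2
    v <- (row$outlier_upper - row$outlier_lower)^2 / 12
  } else {
    pts <- row$outlier_values[[1]]
    m <- mean(pts)
    v <- mean((pts - m)^2)
  }
  c(mean = m, var = v)
}

# The configured mean/sd describe the outlier-including mixture; recover the
# core component's moments so that core + outliers reproduces them.
core_moments <- function(row) {
  r <- row$outlier_rate
  if (r <= 0) return(c(mean = row$mean, sd = row$sd))
  om <- outlier_moments(row)
  m <- row$mean
  v <- row$sd^2
  m_c <- (m - r * om[["mean"]]) / (1 - r)
  v_c <- (v - r * (om[["var"]] + (om[["mean"]] - m)^2)) / (1 - r) -
    (m_c - m)^2
  if (v_c <= 0) {
    stop("outlier specification incompatible with configured mean/sd for ",
         row$group, " at ", row$marker)
  }
  c(mean = m_c, sd = sqrt(v_c))
}

dist_row <- function(dist, fluid, marker) {
  grp <- fluid_group(fluid)
  i <- which(dist$group == grp & dist$marker == marker)
  if (length(i) != 1) {
    stop("no distribution configured for (", fluid, ", ", marker, ")")
  }
  dist[i, ]
}

#' Draw single-source methylation values
#'
#' Draws `n` methylation percentages for one fluid at one marker from the
#' configured reference distribution: a beta distribution (scaled to 0--100)
#' moment-matched to the cell's mean and SD, mixed with the cell's outlier
#' component at its configured rate. A cell with `sd = 0` returns the mean
#' exactly (idealized noiseless mode; outliers are suppressed).
#'
#' Uses the R session RNG; call `set.seed()` for reproducibility.
#'
#' @param fluid A body fluid (or distribution group) name.
#' @param marker Marker short name.
#' @param n Number of draws.
#' @param dist Distribution table, see [marker_distributions()].
#' @param outliers Set `FALSE` to draw from the core component only.
#' @return Numeric vector of length `n`, all values in \[0, 100\].
#' @export
#' @examples
#' set.seed(1)
#' summary(draw_single_source("sperm_secretion", "N27SE", 1000))
draw_single_source <- function(fluid, marker, n = 1,
                               dist = marker_distributions(),
                               outliers = TRUE) {
  row <- dist_row(dist, fluid, marker)
  if (row$sd == 0) return(rep(row$mean, n))
  use_outliers <- outliers && row$outlier_rate > 0
  core <- if (use_outliers) core_moments(row) else
    c(mean = row$mean, sd = row$sd)
  sh <- beta_shapes(core[["mean"]], core[["sd"]])
  x <- 100 * stats::rbeta(n, sh[["shape1"]], sh[["shape2"]])
  if (use_outliers) {
    k <- which(stats::runif(n) < row$outlier_rate)
    if (length(k)) {
      x[k] <- if (row$outlier_kind == "uniform") {
        stats::runif(length(k), row$outlier_lower, row$outlier_upper)
      } else {
        row$outlier_values[[1]][
          sample.int(length(row$outlier_values[[1]]), length(k),
                     replace = TRUE)]
      }
    }
  }
  x
}

#' Specify a (possibly single-component) stain composition
#'
#' @param components Named numeric vector of DNA-mass weights, names being
#'   body fluid names (plus, if generated, `vaginal_postmenopausal`). Weights
#'   must be in (0, 1] and sum to 1 (tolerance 1e-9).
#' @return A `mixture_spec` object.
#' @export
#' @examples
#' mixture_spec(c(menstrual_blood = 0.5, sperm_secretion = 0.5))
mixture_spec <- function(components) {
  if (length(components) < 1) stop("at least one component required")
  allowed <- c(MF_FLUIDS, "vaginal_postmenopausal")
  bad <- setdiff(names(components), allowed)
  if (is.null(names(components)) || length(bad)) {
    stop("unknown fluid(s) in mixture: ", paste(bad, collapse = ", "))
  }
  if (any(duplicated(names(components)))) stop("duplicated mixture component")
  w <- as.numeric(components)
  if (any(w <= 0) || any(w > 1)) stop("weights must lie in (0, 1]")
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  structure(stats::setNames(w, names(components)), class = "mixture_spec")
}

format_composition <- function(spec) {
  paste(sprintf("%s:%g", names(spec), as.numeric(spec)), collapse = ";")
}

parse_composition <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  mixture_spec(stats::setNames(
    vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
    vapply(kv, `[`, character(1), 1)))
}

#' Draw methylation values for a mixed stain
#'
#' The methylation of pooled DNA is modeled as the DNA-mass-weighted
#' arithmetic mean of independent single-source draws for each component.
#'
#' @param spec A [mixture_spec()].
#' @inheritParams draw_single_source
#' @return Numeric vector of length `n` in \[0, 100\].
#' @export
mix_profile <- function(spec, marker, n = 1, dist = marker_distributions(),
                        outliers = TRUE) {
  if (!inherits(spec, "mixture_spec")) spec <- mixture_spec(spec)
  x <- numeric(n)
  for (fluid in names(spec)) {
    x <- x + spec[[fluid]] *
      draw_single_source(fluid, marker, n, dist, outliers)
  }
  clamp01(x)
}

#' Derive the expected rapid-test panel of a composition
#'
#' A pre-test is positive when any component it responds to carries more than
#' `detection_floor` of the DNA mass: the hemoglobin test for any
#' blood-containing fluid (peripheral, menstrual or nasal blood), the amylase
#' test for saliva, the seminal test for sperm secretion. Monotone: adding a
#' triggering component can only turn a test positive.
#'
#' @param spec A [mixture_spec()].
#' @param detection_floor Minimum weight fraction a component needs to trigger
#'   its test, in \[0, 1).
#' @return A [pretest_panel()].
#' @export
#' @examples
#' derive_pretests(mixture_spec(c(menstrual_blood = 0.5, sperm_secretion = 0.5)))
derive_pretests <- function(spec, detection_floor = 0) {
  if (!inherits(spec, "mixture_spec")) spec <- mixture_spec(spec)
  if (detection_floor < 0 || detection_floor >= 1) {
    stop("detection_floor must lie in [0, 1)")
  }
  bf <- body_fluids()
  wt <- function(which_col) {
    fl <- bf$name[bf[[which_col]]]
    sum(as.numeric(spec)[names(spec) %in% fl])
  }
  state <- function(w) if (w > detection_floor) "positive" else "negative"
  pretest_panel(blood = state(wt("triggers_blood")),
                saliva = state(wt("triggers_saliva")),
                sperm = state(wt("triggers_sperm")))
}

#' Generate a synthetic stain cohort as a sample sheet
#'
#' For each design entry, draws latent per-marker methylation values from the
#' component distributions, then emits two replicate measurements per marker
#' by adding independent bounded measurement noise (uniform on +/-
#' `dup_noise` points, so duplicate deviation stays within 2 * `dup_noise`,
#' i.e. the 5-point acceptance bound at the default). QC failures can be
#' injected: `deviation_exceed_rate` replaces one replicate so that the pair
#' deviates by more than the bound; `conversion_fail_rate` marks samples with
#' a failed bisulfite conversion control.
#'
#' Reproducible: the master `seed` deterministically derives one RNG stream
#' per design entry, so identical (design, seed) give identical cohorts.
#'
#' @param design A list of entries `list(spec = <mixture_spec>, n = <count>)`,
#'   or a single `mixture_spec` (with `n` taken from the `n` argument).
#' @param seed Master integer seed.
#' @param n Count used when `design` is a bare `mixture_spec`.
#' @param dup_noise Half-width of the replicate noise, in percentage points.
#' @param deviation_exceed_rate,conversion_fail_rate QC failure injection
#'   rates in \[0, 1\].
#' @param concentration_range Range (ng/ul) of simulated DNA concentrations.
#' @param detection_floor Passed to [derive_pretests()].
#' @param dist,outliers Passed to [mix_profile()].
#' @return A tibble sample sheet: `sample_id`, `true_composition`,
#'   `pretest_blood`, `pretest_saliva`, `pretest_sperm`, `<marker>_rep1`,
#'   `<marker>_rep2` for the six markers, `conversion_control`,
#'   `concentration_ng_ul`.
#' @export
#' @examples
#' design <- list(
#'   list(spec = mixture_spec(c(saliva = 1)), n = 3),
#'   list(spec = mixture_spec(c(nasal_secretion = 0.5,
#'                              vaginal_secretion = 0.5)), n = 2))
#' generate_cohort(design, seed = 11)
generate_cohort <- function(design, seed, n = 1, dup_noise = 2.5,
                            deviation_exceed_rate = 0,
                            conversion_fail_rate = 0,
                            concentration_range = c(2.5, 20),
                            detection_floor = 0,
                            dist = marker_distributions(),
                            outliers = TRUE) {
  if (inherits(design, "mixture_spec")) {
    design <- list(list(spec = design, n = n))
  }
  if (!length(design)) stop("empty cohort design")
  counts <- vapply(design, function(e) as.integer(e$n), integer(1))
  if (any(is.na(counts)) || any(counts < 1)) stop("entry counts must be >= 1")
  set.seed(as.integer(seed))
  entry_seeds <- sample.int(.Machine$integer.max - 1L, length(design))
  blocks <- vector("list", length(design))
  offset <- 0L
  for (e in seq_along(design)) {
    spec <- design[[e]]$spec
    if (!inherits(spec, "mixture_spec")) spec <- mixture_spec(spec)
    ne <- counts[e]
    set.seed(entry_seeds[e])
    pt <- derive_pretests(spec, detection_floor)
    block <- tibble::tibble(
      sample_id = sprintf("S%05d", offset + seq_len(ne)),
      true_composition = format_composition(spec),
      pretest_blood = unname(pt[["blood"]]),
      pretest_saliva = unname(pt[["saliva"]]),
      pretest_sperm = unname(pt[["sperm"]])
    )
    for (mk in MF_MARKERS) {
      latent <- mix_profile(spec, mk, ne, dist, outliers)
      rep1 <- latent + stats::runif(ne, -dup_noise, dup_noise)
      rep2 <- latent + stats::runif(ne, -dup_noise, dup_noise)
      if (deviation_exceed_rate > 0) {
        bad <- stats::runif(ne) < deviation_exceed_rate
        if (any(bad)) {
          push <- sample(c(-1, 1), sum(bad), replace = TRUE) *
            (2 * dup_noise + stats::runif(sum(bad), 1, 6))
          rep2[bad] <- rep1[bad] + push
        }
      }
      block[[paste0(mk, "_rep1")]] <- clamp01(rep1)
      block[[paste0(mk, "_rep2")]] <- clamp01(rep2)
    }
    block$conversion_control <-
      ifelse(stats::runif(ne) < conversion_fail_rate, "fail", "pass")
    block$concentration_ng_ul <-
      stats::runif(ne, concentration_range[1], concentration_range[2])
    blocks[[e]] <- block
    offset <- offset + ne
  }
  do.call(rbind, blocks)
}

#' Convenience design: one single-source block per fluid group
#'
#' @param n_each Samples per fluid.
#' @param fluids Fluid names; defaults to one representative per reference
#'   distribution group.
#' @return A design list for [generate_cohort()].
#' @export
single_source_design <- function(n_each,
                                 fluids = c("nasal_secretion",
                                            "peripheral_blood",
                                            "menstrual_blood", "saliva",
                                            "vaginal_secretion",
                                            "sperm_secretion")) {
  lapply(fluids, function(f) {
    list(spec = mixture_spec(stats::setNames(1, f)), n = n_each)
  })
}

#' Read/write sample sheets
#'
#' Sample sheets are tab-separated text with one row per stain; see
#' [generate_cohort()] for the column layout. Measured sheets from the lab
#' need at least the pre-test columns and `<marker>_rep1`/`_rep2` columns.
#'
#' @param sheet A sample-sheet tibble.
#' @param path File path.
#' @return `read_sample_sheet` returns a tibble; `write_sample_sheet` returns
#'   `path` invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}
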