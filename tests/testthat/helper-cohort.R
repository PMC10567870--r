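# Shared fixtures, built in code.

all_negative <- pretest_panel("negative", "negative", "negative")

# The six single-source fluids with one representative per distribution group.
group_fluids <- c("nasal_secretion", "peripheral_blood", "menstrual_blood",
                  "saliva", "vaginal_secretion", "sperm_secretion")

# Distribution table with all SDs zeroed: every draw is the configured mean.
zero_sd_distributions <- function() {
  d <- marker_distributions()
  d$sd <- 0
  d
}

# Idealized collapsed profile of a pure fluid: every marker at its mean.
mean_profile <- function(fluid, dist = marker_distributions()) {
  grp <- ifelse(fluid %in% c("nasal_secretion", "nasal_blood"),
                "nasal", fluid)
  sub <- dist[dist$group == grp, ]
  stats::setNames(sub$mean, sub$marker)
}

# One-row sample list with duplicate measurements for check_sample().
make_sample <- function(..., conversion = "pass", conc = 5) {
  reps <- list(...)
  c(list(sample_id = "t1", conversion_control = conversion,
         concentration_ng_ul = conc), reps)
}
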