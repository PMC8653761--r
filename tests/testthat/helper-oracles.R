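# Closed-form ML estimates for the balanced one-way random-intercept model
# (g groups of m observations): interior solution from between/within sums
# of squares, boundary solution when the between variance estimate is
# negative.  Independent oracle for the iterative fitter.
one_way_ml <- function(y, g, m) {
  gb <- tapply(y, g, mean)
  N <- length(y)
  ng <- length(gb)
  ssw <- sum((y - gb[g])^2)
  ssb <- m * sum((gb - mean(y))^2)
  sb <- ssb / (ng * m) - ssw / (N - ng) / m
  if (sb > 0) c(group = sb, Residual = ssw / (N - ng))
  else c(group = 0, Residual = (ssw + ssb) / N)
}

# The study's model formula for a given trait and stimulus sex.
male_formula <- function(trait) {
  stats::as.formula(paste(
    trait, "~ date + focal_age + elapsed_min + (1 | focal_male_id) +",
    "(1 | stimulus_id:year) + (1 | year)"))
}

# A fixed design of 87 recordings over 20 stimuli and 6 years used by the
# recovery and coverage studies.
design_87 <- function() {
  cfg <- sim_config(recordings_per_stimulus = c(1:8, 1:8, 1, 2, 5, 7),
                    seed = 100)
  list(cfg = cfg, design = simulate_design(cfg))
}
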