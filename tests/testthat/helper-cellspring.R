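# Shared fixture builders; everything is generated in code.

# a perfectly linear approach-only curve F = slope * displacement
line_curve <- function(slope = 1000, span = 3e-6, n = 300, instrument = "micro") {
  d <- seq(0, span, length.out = n)
  force_curve(d, slope * d, instrument = instrument)
}

# approach + retract curve from explicit depth/force functions on [0, span]
loop_curve <- function(f_app, f_ret, span = 1e-6, n = 1000, instrument = "micro") {
  d <- seq(0, span, length.out = n)
  force_curve(
    displacement = c(d, rev(d)),
    force = c(f_app(d), rev(f_ret(d))),
    segment = rep(c("approach", "retract"), each = n),
    instrument = instrument
  )
}

# the reference parameter vector used across inference tests
kappa_star <- function() spring_params(10, 5, 20, 5, 3, 2)

model_means <- function(params = kappa_star(), ratios = ratio_set()) {
  stats::setNames(
    effective_stiffness(treatment_levels(), params, ratios),
    treatment_levels()
  )
}

# dataset whose sample mean sits exactly at the model mean with a chosen se
dataset_with_se <- function(means, se = 1, n = 4) {
  dataset_from_summary(means, n = n, sd = se * sqrt(n))
}

max_rel_err <- function(est, truth) max(abs(est - truth) / truth)
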