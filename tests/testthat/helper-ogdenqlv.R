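# shared fixtures: all built in code at test time

# a reduced-cost fit configuration for module-level tests; acceptance tests
# use the package defaults
quick_config <- function(...) {
  args <- utils::modifyList(list(n_starts = 4, n_steps = 400,
                                 maxiter = 150), list(...))
  do.call(fit_config, args)
}

# small noiseless three-rate dataset generated from a material
noiseless_curves <- function(material, mode = "simple_shear",
                             max_strain = 1.0, n_points = 51,
                             rates = c(0.01, 150, 300)) {
  d <- experiment_design(mode, rates, n = 1, max_strain = max_strain,
                         n_points = n_points)
  reps <- generate_replicates(material, d, noise_model(a = 0, b = 0),
                              n_steps = 400)
  reps$truth
}

# the viscoelastic reference materials (one-term Ogden + one-term Prony)
qlv_presets <- function() {
  p <- preset_materials()
  p[c("cerebrum", "cerebellum", "brainstem", "vasculature")]
}
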