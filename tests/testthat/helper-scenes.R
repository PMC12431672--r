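# Shared fixtures built in code: quick stacks and a full two-population
# imaging experiment (simulate -> reconstruct -> mask -> summarize ->
# image-level ANOVA decision) used by the power / type-I properties.

quick_acq <- function(...) flim_acquisition(...)

# One simulated image -> image-level masked mean tau_phi.
image_mean_tau_phi <- function(scene, acq, ref, seed) {
  stk <- simulate_stack(scene, acq, seed = seed)
  rec <- flim_reconstruct(stk, ref)
  mask <- otsu_mask(rec$lifetime$norm_intensity)
  summarize_masked(rec$lifetime, mask)$mean_tau_phi
}

# Full experiment: n_images per group, two cell populations whose
# mixtures are given per group; returns the ANOVA p-value on the
# image-level means.
experiment_p_value <- function(seed, mixtures_by_group, n_images = 10,
                               dim = c(48L, 48L), n_cells = c(2L, 2L),
                               photons_per_cell = 2e4) {
  acq <- quick_acq()
  ref <- reference_stack(acq, photons = 2000, dim = dim, noiseless = TRUE)
  set.seed(seed)
  means <- c(); labels <- c()
  for (g in seq_along(mixtures_by_group)) {
    mixg <- mixtures_by_group[[g]]
    for (i in seq_len(n_images)) {
      scene <- two_population_scene(
        dim = dim, n_cells = n_cells, mixtures = mixg,
        photons_per_cell = photons_per_cell,
        n_phases = acq$n_phases,
        seed = seed * 1000L + g * 100L + i)
      means <- c(means,
                 image_mean_tau_phi(scene, acq, ref,
                                    seed = seed * 1000L + g * 100L + i + 7L))
      labels <- c(labels, paste0("group", g))
    }
  }
  one_way_anova(means, labels)$p
}
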