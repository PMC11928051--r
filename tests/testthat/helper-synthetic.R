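# shared fixtures: small noiseless and noisy synthetic clades, built in code

noiseless_spec <- function(n_species = 12) {
  synth_clade_spec(n_species = n_species, sigma_species = 0,
                   sigma_meas = 0, missing_kinematics = 0,
                   n_obs_range = c(1L, 1L))
}

make_clade <- function(n_species = 12, seed = 101, spec = NULL) {
  if (is.null(spec)) spec <- noiseless_spec(n_species)
  tree <- synth_tree(spec$n_species, seed = seed)
  nat <- synth_observations(spec, tree, seed = seed + 1L)
  list(tree = tree, native = nat, obs = as_observations(nat))
}

# native-unit rows for ingest tests
native_row <- function(species = "Drosophila melanogaster", mass_mg = 1,
                       wing_length_mm = 2.5, wing_area_mm2 = 2,
                       body_length_mm = NA, frequency_hz = 200,
                       amplitude_deg = 150, pitch_deg = 45,
                       altitude_m = NA, density_kgm3 = NA,
                       n_meas = 1, source = "test") {
  data.frame(species, mass_mg, wing_length_mm, wing_area_mm2,
             body_length_mm, frequency_hz, amplitude_deg, pitch_deg,
             altitude_m, density_kgm3, n_meas, source,
             stringsAsFactors = FALSE)
}
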