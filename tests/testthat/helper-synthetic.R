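# shared fixture builders

std_condition <- function(acid_conc = 0.005, ...) {
  experiment_condition(solvent_gvl_massfrac = 0.9, acid_name = "HCl",
                       acid_conc = acid_conc, ...)
}

# one synthetic profile with sampling scaled to the half-life so every
# rate constant is observed over a comparable conversion window
make_profile <- function(k, acid_conc = 0.005, noise_cv = 0, seed = 1,
                         selectivity = 0.8, k_deg = 0, n_times = 20,
                         isotope = "H") {
  t_half <- log(2) / (k * acid_conc)
  spec <- generator_spec(
    std_condition(acid_conc, isotope = isotope), true_k = k,
    selectivity = selectivity, k_deg = k_deg, noise_cv = noise_cv,
    sample_times = c(0, seq(0.2, 4, length.out = n_times - 1)) * t_half,
    seed = seed)
  simulate_profile(spec, 1)
}
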