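# Bundled literature benchmark tables for acid-catalyzed fructose
# dehydration to HMF (373 K rate constants, 393 K yields at ~90%
# conversion; 95% confidence bounds).  Shipped as plain CSV under
# inst/extdata and loaded on demand.

ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "chlorkin",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Benchmark rate constants for homogeneous acids across solvents
#'
#' Fructose conversion rate constants (M^-1 ks^-1, 373 K) and HMF yields
#' (%, 393 K at ~90% conversion) for H2SO4, triflic acid and HCl in
#' water, 90% GVL, 90% THF and 90% dioxane (each with 10% water).
#'
#' @return data.frame with columns `solvent`, `acid`, `k_M1ks1`,
#'   `k_ci95`, `hmf_yield_pct`, `yield_ci95`.
#' @export
reference_acid_table <- function() ref_csv("acid_rate_constants.csv")

#' Benchmark rate constants for acid/salt systems in 90% GVL
#'
#' Fructose conversion rate constants (M^-1 ks^-1, 373 K) for combinations
#' of strong acids with chloride, bromide, iodide and fluoride salts in
#' 90% GVL/10% water.  The acid-free KCl row is referenced to the salt
#' concentration (r = k [R] [Salt]).
#'
#' @return data.frame with columns `acid`, `salt`, `k_M1ks1`, `k_ci95`,
#'   `note`.
#' @export
reference_salt_table <- function() ref_csv("salt_rate_constants.csv")

#' Benchmark free-energy components for fructose dehydration
#'
#' Computed oxocarbenium-ion formation free energies, proton-abstraction
#' barriers and apparent (total) activation free energies, kJ mol^-1, for
#' water and GVL/water systems with various catalyst/anion combinations.
#' Rows whose components carry corrections keep a provenance note.
#'
#' @return data.frame with columns `system`, `catalyst_anion`,
#'   `dG_formation_kJmol`, `dG_abstraction_kJmol`, `dG_total_kJmol`,
#'   `note`.
#' @export
reference_free_energy_table <- function() ref_csv("free_energy_components.csv")
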