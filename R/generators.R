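# Synthetic batch-kinetics generator.
#
# Reaction network (pseudo-first-order in the catalyst):
#   F  --s * k [H+]-->        HMF        (branch fraction `selectivity`)
#   F  --(1-s) * k [H+]-->    humins     (unobserved)
#   HMF --k_deg [H+]-->       levulinic acid
# Closed forms of the consecutive scheme are used, so noiseless profiles
# satisfy the analytic solutions to machine precision.

# log-normal multiplicative noise with unit mean and relative sd `cv`
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generator specification for synthetic kinetic profiles
#'
#' Bundles the true kinetic parameters and sampling design used by
#' [simulate_profile()].  Defaults reproduce a typical experiment:
#' 50 mM fructose, 5 mM acid, rate constants on the scale reported for
#' strong acids in 90% GVL.
#'
#' @param conditions list of [experiment_condition()] objects.
#' @param true_k second-order rate constants, M^-1 ks^-1, one per
#'   condition (recycled if scalar).
#' @param selectivity fraction of reactant flux routed to the primary
#'   product, in [0,1].
#' @param k_deg degradation rate constant of the primary product,
#'   M^-1 ks^-1.
#' @param noise_cv relative (multiplicative, log-normal) noise coefficient
#'   of variation; 0.05 emulates HPLC-like measurement error.
#' @param sample_times sampling times, ks.
#' @param r0 initial reactant concentration, M.
#' @param seed integer seed; all noise is reproducible from it.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(conditions,
                           true_k,
                           selectivity = 0.8,
                           k_deg = 0,
                           noise_cv = 0.05,
                           sample_times = seq(0, 6, by = 0.3),
                           r0 = 0.050,
                           seed = 1L) {
  if (inherits(conditions, "experiment_condition"))
    conditions <- list(conditions)
  stopifnot(length(conditions) >= 1)
  true_k <- rep_len(as.numeric(true_k), length(conditions))
  if (any(true_k < 0) || k_deg < 0)
    stop("rate constants must be >= 0", call. = FALSE)
  if (selectivity < 0 || selectivity > 1)
    stop("selectivity must lie in [0, 1]", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  sample_times <- as.numeric(sample_times)
  if (any(sample_times < 0))
    stop("sample_times must be nonnegative", call. = FALSE)
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing", call. = FALSE)
  if (r0 <= 0) stop("r0 must be > 0", call. = FALSE)
  structure(list(conditions = conditions, true_k = true_k,
                 selectivity = selectivity, k_deg = k_deg,
                 noise_cv = noise_cv, sample_times = sample_times,
                 r0 = r0, seed = as.integer(seed)),
            class = "generator_spec")
}

# noise-free closed forms of the branched consecutive scheme
profile_closed_form <- function(t, r0, kF, kD, selectivity) {
  R <- r0 * exp(-kF * t)
  if (kF == 0) {
    P <- rep(0, length(t)); S <- rep(0, length(t))
  } else if (abs(kD - kF) < 1e-12 * max(kF, kD)) {
    P <- selectivity * kF * r0 * t * exp(-kF * t)
    S <- selectivity * (r0 - R) - P
  } else {
    P <- selectivity * kF * r0 * (exp(-kF * t) - exp(-kD * t)) / (kD - kF)
    S <- selectivity * (r0 - R) - P
  }
  list(reactant = R, primary = P, secondary = pmax(S, 0))
}

#' Simulate one batch kinetic profile
#'
#' Reactant decays as R(t) = R0 exp(-k [H+] t); the primary product follows
#' the consecutive-reaction closed form with branching fraction
#' `selectivity`; the remainder of the converted reactant is routed to
#' unobserved condensation byproducts (humins).  Multiplicative log-normal
#' noise with CV `noise_cv` is applied to every reported concentration.
#'
#' @param spec a [generator_spec()].
#' @param condition one of `spec$conditions` (or its index).
#' @return a [kinetic_profile()].
#' @export
simulate_profile <- function(spec, condition = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.numeric(condition)) {
    idx <- as.integer(condition)
    if (idx < 1 || idx > length(spec$conditions))
      stop("condition index out of range", call. = FALSE)
  } else {
    idx <- Position(function(c) identical(c, condition), spec$conditions)
    if (is.na(idx) || is.null(idx))
      stop("condition not present in generator spec", call. = FALSE)
  }
  cond <- spec$conditions[[idx]]
  cat_conc <- catalyst_conc(cond)
  if (cat_conc <= 0)
    stop("condition has no catalyst (acid and salt both zero)",
         call. = FALSE)
  kF <- spec$true_k[idx] * cat_conc
  kD <- spec$k_deg * cat_conc
  t <- spec$sample_times
  cf <- profile_closed_form(t, spec$r0, kF, kD, spec$selectivity)
  # per-condition substream so each profile is reproducible on its own
  set.seed(spec$seed + idx - 1L)
  n <- length(t)
  kinetic_profile(cond, t,
                  reactant = cf$reactant * lnorm_noise(n, spec$noise_cv),
                  primary = cf$primary * lnorm_noise(n, spec$noise_cv),
                  secondary = cf$secondary * lnorm_noise(n, spec$noise_cv))
}

#' Chloride-sweep design for rate-constant tables
#'
#' Describes the study design behind rate-constant-versus-chloride curves:
#' a set of GVL/water solvent mixtures, each with its own chloride-free
#' rate constant `k_o` and transition-state binding constant `K_Cl`, a
#' shared enhancement factor, and a chloride concentration grid.
#'
#' The defaults encode five solvent mixtures (5-90% GVL) whose `k_o` and
#' `K_Cl` follow the linear relation between the chloride-free rate
#' constant and the binding constant observed across GVL/water systems
#' (k_o = 0.84 K_Cl - 0.87), with a shared enhancement of 5 and a chloride
#' grid spanning 5 mM to 2.5 M.
#'
#' @param solvent_fractions GVL mass fractions in [0,1].
#' @param k_o chloride-free rate constants per solvent, M^-1 ks^-1 (> 0).
#' @param K_Cl transition-state binding constants per solvent, M^-1 (>= 0).
#' @param r_enhance shared dimensionless enhancement factor (>= 0).
#' @param cl_grid chloride concentrations, M (>= 0).
#' @return an object of class `chloride_design`.
#' @export
chloride_design <- function(solvent_fractions = c(0.05, 0.25, 0.50, 0.75, 0.90),
                            K_Cl = c(1.2, 2.5, 5, 12, 25),
                            k_o = 0.84 * K_Cl - 0.87,
                            r_enhance = 5,
                            cl_grid = c(0, 0.005, 0.025, 0.1, 0.25,
                                        0.5, 1, 2.5)) {
  solvent_fractions <- as.numeric(solvent_fractions)
  if (any(solvent_fractions < 0 | solvent_fractions > 1))
    stop("solvent fractions must lie in [0, 1]", call. = FALSE)
  k_o <- rep_len(as.numeric(k_o), length(solvent_fractions))
  K_Cl <- rep_len(as.numeric(K_Cl), length(solvent_fractions))
  if (any(k_o <= 0)) stop("k_o must be > 0", call. = FALSE)
  if (any(K_Cl < 0)) stop("K_Cl must be >= 0", call. = FALSE)
  if (r_enhance < 0) stop("r_enhance must be >= 0", call. = FALSE)
  if (any(cl_grid < 0))
    stop("chloride concentrations must be >= 0", call. = FALSE)
  structure(list(solvent_fractions = solvent_fractions, k_o = k_o,
                 K_Cl = K_Cl, r_enhance = r_enhance,
                 cl_grid = as.numeric(cl_grid)),
            class = "chloride_design")
}

#' Generate a rate-constant-versus-chloride table
#'
#' Applies the saturation-enhancement law
#' k_obs = k_o [1 + r_enhance K_Cl cl / (1 + K_Cl cl)] per solvent over
#' the chloride grid, then multiplies by log-normal noise with CV
#' `noise_cv`.  Deterministic given `seed`.
#'
#' @param design a [chloride_design()].
#' @param noise_cv relative noise CV (default 0.05).
#' @param seed integer seed.
#' @return a data.frame with columns `solvent` (GVL mass fraction),
#'   `cl_M` and `k_obs` (M^-1 ks^-1).
#' @export
generate_chloride_table <- function(design, noise_cv = 0.05, seed = 1L) {
  stopifnot(inherits(design, "chloride_design"))
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(design$solvent_fractions), function(i) {
    k_true <- enhanced_rate(design$k_o[i], design$r_enhance,
                            design$K_Cl[i], design$cl_grid)
    data.frame(solvent = design$solvent_fractions[i],
               cl_M = design$cl_grid,
               k_obs = k_true * lnorm_noise(length(k_true), noise_cv))
  })
  do.call(rbind, rows)
}

#' Generate an Arrhenius rate-constant table
#'
#' k(T) = exp(lnA - Ea / (R T)) times log-normal noise with CV `noise_cv`.
#'
#' @param Ea apparent activation energy, kJ mol^-1.
#' @param lnA natural log of the pre-exponential factor (rate-constant
#'   units of the profile).
#' @param temperatures temperatures in K (> 0, at least one).
#' @param noise_cv relative noise CV.
#' @param seed integer seed.
#' @return a data.frame with columns `T_K` and `k`.
#' @export
generate_arrhenius_set <- function(Ea, lnA, temperatures,
                                   noise_cv = 0, seed = 1L) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) == 0)
    stop("temperature list must not be empty", call. = FALSE)
  if (any(temperatures <= 0))
    stop("temperatures must be > 0 K", call. = FALSE)
  set.seed(as.integer(seed))
  k <- exp(lnA - Ea / (R_GAS * temperatures)) *
    lnorm_noise(length(temperatures), noise_cv)
  data.frame(T_K = temperatures, k = k)
}
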