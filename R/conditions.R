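#' Gas constant in kJ mol^-1 K^-1
#'
#' CODATA value used throughout for Arrhenius and Eyring arithmetic.
#' @export
R_GAS <- 8.314462618e-3

ANIONS <- c("Cl-", "Br-", "I-", "F-", "TfO-", "HSO4-", "none")

#' Experimental condition metadata
#'
#' Describes one batch experiment: the solvent (GVL mass fraction, or a
#' named solvent such as THF or dioxane), the Bronsted acid and its
#' concentration, an optional salt, the temperature and the solvent
#' isotope.  Every kinetic profile and every fit is keyed by one of these.
#'
#' @param solvent_gvl_massfrac GVL mass fraction in [0,1]; ignored when
#'   `solvent_name` is given.
#' @param acid_name acid identity, e.g. "HCl", "H2SO4", "triflic".
#' @param acid_conc acid concentration in M (>= 0; 0 means salt-only).
#' @param salt_name salt identity or `NA` for none.
#' @param salt_conc salt concentration in M.
#' @param anion anion label, one of `"Cl-"`, `"Br-"`, `"I-"`, `"F-"`,
#'   `"TfO-"`, `"HSO4-"`, `"none"`.
#' @param temperature temperature in K (> 0).
#' @param isotope `"H"` or `"D"` (solvent isotope, for KIE work).
#' @param solvent_name optional named solvent ("water", "THF", "dioxane",
#'   "GVL"); when given, labels override the mass-fraction descriptor.
#' @return an object of class `experiment_condition` (a named list).
#' @export
experiment_condition <- function(solvent_gvl_massfrac = 0,
                                 acid_name = "HCl",
                                 acid_conc = 0.005,
                                 salt_name = NA_character_,
                                 salt_conc = 0,
                                 anion = "none",
                                 temperature = 373,
                                 isotope = "H",
                                 solvent_name = NULL) {
  if (!is.numeric(solvent_gvl_massfrac) || solvent_gvl_massfrac < 0 ||
      solvent_gvl_massfrac > 1)
    stop("solvent_gvl_massfrac must lie in [0, 1]", call. = FALSE)
  if (acid_conc < 0 || salt_conc < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  if (temperature <= 0)
    stop("temperature must be > 0 K", call. = FALSE)
  anion <- match.arg(anion, ANIONS)
  isotope <- match.arg(isotope, c("H", "D"))
  structure(list(
    solvent_gvl_massfrac = as.numeric(solvent_gvl_massfrac),
    solvent_name = if (is.null(solvent_name)) NA_character_ else solvent_name,
    acid_name = acid_name,
    acid_conc = as.numeric(acid_conc),
    salt_name = salt_name,
    salt_conc = as.numeric(salt_conc),
    anion = anion,
    temperature = as.numeric(temperature),
    isotope = isotope
  ), class = "experiment_condition")
}

#' @export
print.experiment_condition <- function(x, ...) {
  solv <- if (!is.na(x$solvent_name)) x$solvent_name else
    sprintf("%.0f%% GVL/%.0f%% H2O", 100 * x$solvent_gvl_massfrac,
            100 * (1 - x$solvent_gvl_massfrac))
  cat(sprintf("<condition> %s | %s %.4g M", solv, x$acid_name, x$acid_conc))
  if (!is.na(x$salt_name) && x$salt_conc > 0)
    cat(sprintf(" | %s %.4g M", x$salt_name, x$salt_conc))
  cat(sprintf(" | %g K | %s\n", x$temperature, x$isotope))
  invisible(x)
}

#' Kinetic profile container
#'
#' A concentration-time series from one batch experiment: reactant
#' (fructose), primary product (HMF) and secondary product (levulinic
#' acid), in M against time in ks.
#'
#' @param condition an [experiment_condition()].
#' @param times sampling times in ks, strictly increasing, >= 0.
#' @param reactant reactant concentrations, M.
#' @param primary primary-product concentrations, M (default zeros).
#' @param secondary secondary-product concentrations, M (default zeros).
#' @return an object of class `kinetic_profile`.
#' @export
kinetic_profile <- function(condition, times, reactant,
                            primary = NULL, secondary = NULL) {
  stopifnot(inherits(condition, "experiment_condition"))
  times <- as.numeric(times)
  if (length(times) == 0) stop("profile has no time points", call. = FALSE)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  reactant <- as.numeric(reactant)
  if (length(reactant) != length(times))
    stop("reactant length must match times", call. = FALSE)
  if (any(reactant < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (is.null(primary)) primary <- rep(0, length(times))
  if (is.null(secondary)) secondary <- rep(0, length(times))
  if (length(primary) != length(times) || length(secondary) != length(times))
    stop("product series must match times", call. = FALSE)
  if (any(primary < 0) || any(secondary < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  structure(list(condition = condition, times = times,
                 reactant = reactant, primary = as.numeric(primary),
                 secondary = as.numeric(secondary)),
            class = "kinetic_profile")
}

#' @export
print.kinetic_profile <- function(x, ...) {
  cat(sprintf("<kinetic_profile> %d points, t = %.3g..%.3g ks, R0 = %.4g M\n",
              length(x$times), min(x$times), max(x$times), x$reactant[1]))
  print(x$condition)
  invisible(x)
}

#' @export
as.data.frame.kinetic_profile <- function(x, ...) {
  data.frame(
    time_ks = rep(x$times, 3),
    species = rep(c("reactant", "primary", "secondary"),
                  each = length(x$times)),
    conc_M = c(x$reactant, x$primary, x$secondary)
  )
}

# effective catalyst concentration: [H+] normally, [Salt] in salt-only mode
catalyst_conc <- function(condition) {
  if (condition$acid_conc > 0) condition$acid_conc else condition$salt_conc
}
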