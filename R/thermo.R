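# Arrhenius regression, apparent-barrier bookkeeping and an Eyring bridge.

#' Fit Arrhenius parameters from rate constants at several temperatures
#'
#' Ordinary least squares of ln k on 1/T (the conventional linearization):
#' Ea = -slope * R and lnA = intercept, with Wald confidence intervals
#' from the regression covariance.  `method = "nonlinear"` instead fits
#' k = exp(lnA - Ea/(R T)) directly by Levenberg-Marquardt.
#'
#' @param table data.frame with columns `T_K` (K) and `k` (> 0).
#' @param method `"linear"` (default, log-space OLS) or `"nonlinear"`.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `arrhenius_fit`: `Ea` (kJ mol^-1), `lnA`,
#'   `Ea_ci`, `lnA_ci`, `r_squared`.
#' @export
fit_arrhenius <- function(table, method = c("linear", "nonlinear"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), all(c("T_K", "k") %in% names(table)))
  if (nrow(table) < 2) stop("need at least 2 temperatures", call. = FALSE)
  if (any(table$T_K <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
  if (any(table$k <= 0))
    stop("rate constants must be > 0 for Arrhenius analysis", call. = FALSE)
  x <- 1 / table$T_K
  y <- log(table$k)
  lmfit <- stats::lm(y ~ x)
  cf <- stats::coef(lmfit)
  Ea <- -unname(cf[2]) * R_GAS
  lnA <- unname(cf[1])
  n <- nrow(table)
  if (n > 2) {
    X <- cbind(1, x)
    sigma2 <- sum(stats::resid(lmfit)^2) / (n - 2)
    se <- sqrt(diag(sigma2 * solve(crossprod(X))))
    tq <- stats::qt(1 - (1 - conf_level) / 2, n - 2)
    Ea_ci <- sort(-(cf[2] + c(-1, 1) * tq * se[2]) * R_GAS)
    lnA_ci <- cf[1] + c(-1, 1) * tq * se[1]
  } else {
    Ea_ci <- c(NA_real_, NA_real_); lnA_ci <- c(NA_real_, NA_real_)
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(lmfit)^2) / ss_tot else 1
  if (method == "nonlinear") {
    fit <- minpack.lm::nls.lm(
      par = c(lnA = lnA, Ea = Ea),
      fn = function(p) table$k - exp(p[1] - p[2] / (R_GAS * table$T_K)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    lnA <- unname(fit$par[1]); Ea <- unname(fit$par[2])
    sse <- sum(fit$fvec^2)
    if (n > 2) {
      sigma2 <- sse / (n - 2)
      covm <- tryCatch(sigma2 * solve(fit$hessian),
                       error = function(e) matrix(NA_real_, 2, 2))
      tq <- stats::qt(1 - (1 - conf_level) / 2, n - 2)
      lnA_ci <- lnA + c(-1, 1) * tq * sqrt(covm[1, 1])
      Ea_ci <- Ea + c(-1, 1) * tq * sqrt(covm[2, 2])
    }
    ss_tot_k <- sum((table$k - mean(table$k))^2)
    r2 <- if (ss_tot_k > 0) 1 - sse / ss_tot_k else 1
  }
  structure(list(Ea = Ea, lnA = lnA,
                 Ea_ci = unname(Ea_ci), lnA_ci = unname(lnA_ci),
                 r_squared = max(min(r2, 1), 0), method = method,
                 data = table),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.4g kJ mol^-1, lnA = %.4g (%s)\n",
              x$Ea, x$lnA, x$method))
  if (all(is.finite(x$Ea_ci)))
    cat(sprintf("  Ea 95%% CI [%.4g, %.4g]; lnA 95%% CI [%.4g, %.4g]\n",
                x$Ea_ci[1], x$Ea_ci[2], x$lnA_ci[1], x$lnA_ci[2]))
  cat(sprintf("  R^2 (ln k vs 1/T) = %.4f, n = %d\n", x$r_squared,
              nrow(x$data)))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(Ea = object$Ea, lnA = object$lnA)
}

#' @export
predict.arrhenius_fit <- function(object, temperatures = object$data$T_K,
                                  ...) {
  exp(object$lnA - object$Ea / (R_GAS * temperatures))
}

#' Assemble an apparent free-energy barrier from its components
#'
#' The apparent activation barrier for acid-catalyzed fructose dehydration
#' is the sum of the reaction free energy to form the oxocarbenium ion
#' (protonation of the C2 hydroxyl plus water elimination) and the
#' activation free energy for water to deprotonate that ion.
#'
#' @param dG_formation oxocarbenium-ion formation free energy, kJ mol^-1.
#' @param dG_abstraction proton-abstraction activation free energy,
#'   kJ mol^-1 (>= 0).
#' @param system label, e.g. "90% GVL + H+/Cl-".
#' @param note optional provenance note (e.g. a correction applied to a
#'   component).
#' @return object of class `free_energy_profile` with `dG_total` equal to
#'   the exact sum of the components.
#' @export
assemble_profile <- function(dG_formation, dG_abstraction,
                             system = "", note = NA_character_) {
  if (!is.finite(dG_formation) || !is.finite(dG_abstraction))
    stop("free-energy components must be finite", call. = FALSE)
  if (dG_abstraction < 0)
    stop("abstraction barrier must be >= 0", call. = FALSE)
  structure(list(system = system,
                 dG_formation = as.numeric(dG_formation),
                 dG_abstraction = as.numeric(dG_abstraction),
                 dG_total = as.numeric(dG_formation) +
                   as.numeric(dG_abstraction),
                 note = note),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<free_energy_profile> %s: %g (formation) + %g (abstraction) = %g kJ mol^-1\n",
    x$system, x$dG_formation, x$dG_abstraction, x$dG_total))
  if (!is.na(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' Difference of apparent barriers between two systems
#'
#' @param profile_a,profile_b [assemble_profile()] results.
#' @return dG_total(b) - dG_total(a) in kJ mol^-1 (negative when b has the
#'   lower barrier).
#' @export
barrier_delta <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "free_energy_profile"),
            inherits(profile_b, "free_energy_profile"))
  profile_b$dG_total - profile_a$dG_total
}

#' Eyring rate ratio implied by a barrier difference
#'
#' exp(-(dG_a - dG_b) / (R T)): the factor by which system a is faster
#' than system b if the barriers alone controlled the rates.  Used only
#' for qualitative trend comparison against measured rate constants.
#'
#' @param dG_a,dG_b apparent barriers, kJ mol^-1.
#' @param T temperature in K (> 0).
#' @return dimensionless rate ratio k_a / k_b.
#' @export
eyring_rate_ratio <- function(dG_a, dG_b, T = 373) {
  if (T <= 0) stop("temperature must be > 0 K", call. = FALSE)
  exp(-(dG_a - dG_b) / (R_GAS * T))
}
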