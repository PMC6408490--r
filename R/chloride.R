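# Chloride transition-state saturation-enhancement model.
#
# The rate-determining transition state R‡ binds a chloride ion,
#   Cl- + R‡  <=>  RCl‡   (equilibrium constant K_Cl, M^-1),
# and the reaction proceeds through both forms.  With the bound fraction
#   f = K_Cl [Cl-] / (1 + K_Cl [Cl-])
# and enhancement factor r_enhance = r_Cl / r_o, the observed rate
# constant is
#   k_obs = k_o [1 + r_enhance f].
# Fitted per solvent, or globally over several solvent mixtures with a
# single shared r_enhance and per-solvent (k_o, K_Cl).  Residuals are
# scaled by the model value (relative weighting) so solvents whose rate
# constants span orders of magnitude contribute comparably.

#' Fraction of transition states bound to chloride
#'
#' @param K_Cl binding constant, M^-1 (>= 0).
#' @param cl_conc chloride concentration, M (>= 0); vectorized.
#' @return K_Cl cl / (1 + K_Cl cl), in [0, 1].
#' @export
saturation_fraction <- function(K_Cl, cl_conc) {
  if (any(K_Cl < 0) || any(cl_conc < 0))
    stop("K_Cl and cl_conc must be >= 0", call. = FALSE)
  x <- K_Cl * cl_conc
  x / (1 + x)
}

#' Chloride-enhanced rate constant
#'
#' k_o [1 + r_enhance K_Cl cl / (1 + K_Cl cl)]: strictly increasing and
#' concave down in chloride concentration for positive parameters, rising
#' from k_o at zero chloride to the plateau k_o (1 + r_enhance).
#'
#' @param r_o chloride-free rate-constant scale (>= 0).
#' @param r_enhance dimensionless enhancement factor (>= 0).
#' @param K_Cl binding constant, M^-1 (>= 0).
#' @param cl_conc chloride concentration, M (>= 0); vectorized.
#' @return rate-constant values on the scale of `r_o`.
#' @export
enhanced_rate <- function(r_o, r_enhance, K_Cl, cl_conc) {
  if (any(r_o < 0) || any(r_enhance < 0))
    stop("r_o and r_enhance must be >= 0", call. = FALSE)
  r_o * (1 + r_enhance * saturation_fraction(K_Cl, cl_conc))
}

# starting values from the data shape: baseline from the smallest-cl
# point, enhancement from the plateau/baseline ratio, K_Cl from the
# chloride level nearest the half rise
init_single <- function(cl, k) {
  o <- order(cl)
  cl <- cl[o]; k <- k[o]
  r_o0 <- max(k[1], .Machine$double.eps)
  plateau <- max(k)
  r_e0 <- max(plateau / r_o0 - 1, 1e-3)
  half <- r_o0 * (1 + r_e0 / 2)
  i <- which(k >= half)[1]
  cl_half <- if (!is.na(i) && cl[i] > 0) cl[i] else max(cl[cl > 0], 1e-3)
  c(r_o = r_o0, r_enhance = r_e0, K_Cl = 1 / cl_half)
}

wald_ci <- function(est, covm, dof, level = 0.95) {
  tq <- stats::qt(1 - (1 - level) / 2, max(dof, 1))
  se <- sqrt(pmax(diag(covm), 0))
  cbind(low = est - tq * se, high = est + tq * se)
}

#' Fit the chloride saturation-enhancement model
#'
#' Fits k_obs(cl) = k_o [1 + r_enhance K_Cl cl / (1 + K_Cl cl)] to one or
#' several rate-constant-versus-chloride tables by Levenberg-Marquardt
#' least squares with relative (divide-by-model) weighting.  With more
#' than one solvent the enhancement factor is shared across solvents by
#' default while k_o and K_Cl stay solvent-specific; `shared = FALSE`
#' frees r_enhance per solvent, and an F test for the shared-parameter
#' restriction is reported either way.
#'
#' @param table data.frame with columns `cl_M` and `k_obs`, plus `solvent`
#'   for multi-solvent fits (any label; single-solvent tables may omit it).
#' @param shared share r_enhance across solvents (default TRUE).
#' @param weighting `"relative"` (default; residuals divided by the model
#'   value) or `"absolute"`.
#' @param conf_level confidence level for Wald intervals.
#' @return an object of class `chloride_fit`: `per_solvent` data.frame
#'   (solvent, r_o, K_Cl, r_enhance and Wald CIs, per-solvent R^2),
#'   `r_enhance` (shared value or named vector), `shared`, `sse`,
#'   `f_test` comparing shared vs free enhancement, and the data.
#' @export
fit_chloride <- function(table, shared = TRUE,
                         weighting = c("relative", "absolute"),
                         conf_level = 0.95) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(table), all(c("cl_M", "k_obs") %in% names(table)))
  if (any(table$cl_M < 0))
    stop("chloride concentrations must be >= 0", call. = FALSE)
  if (any(table$k_obs <= 0))
    stop("observed rate constants must be > 0", call. = FALSE)
  if (!"solvent" %in% names(table)) table$solvent <- "solvent"
  solvents <- unique(table$solvent)
  ns <- length(solvents)
  for (s in solvents) {
    ncl <- length(unique(table$cl_M[table$solvent == s]))
    if (ncl < 4)
      stop(sprintf("solvent %s has %d distinct chloride levels; need >= 4",
                   s, ncl), call. = FALSE)
  }

  fit_one <- function(sub) {
    single_solvent_fit(sub$cl_M, sub$k_obs, weighting, conf_level)
  }

  if (ns == 1) {
    one <- fit_one(table)
    per <- data.frame(solvent = solvents, r_o = one$par["r_o"],
                      K_Cl = one$par["K_Cl"],
                      r_o_low = one$ci["r_o", 1], r_o_high = one$ci["r_o", 2],
                      K_Cl_low = one$ci["K_Cl", 1],
                      K_Cl_high = one$ci["K_Cl", 2],
                      r_squared = one$r_squared, row.names = NULL)
    out <- list(per_solvent = per, r_enhance = unname(one$par["r_enhance"]),
                r_enhance_ci = one$ci["r_enhance", ], shared = TRUE,
                sse = one$sse, f_test = NULL, weighting = weighting,
                identifiable = one$identifiable, data = table)
    class(out) <- "chloride_fit"
    return(out)
  }

  # free-enhancement fit: independent per-solvent fits
  free_fits <- lapply(solvents, function(s)
    fit_one(table[table$solvent == s, ]))
  sse_free <- sum(vapply(free_fits, function(f) f$sse, 0))

  # shared-enhancement fit: parameters (log r_e, log r_o[i], log K_Cl[i])
  shared_fit <- global_shared_fit(table, solvents, free_fits, weighting)
  sse_shared <- shared_fit$sse

  n_obs <- nrow(table)
  p_free <- 3 * ns
  p_shared <- 2 * ns + 1
  df1 <- p_free - p_shared
  df2 <- n_obs - p_free
  f_stat <- if (df2 > 0 && sse_free > 0)
    ((sse_shared - sse_free) / df1) / (sse_free / df2) else NA_real_
  f_test <- list(statistic = f_stat, df1 = df1, df2 = df2,
                 p_value = if (is.finite(f_stat))
                   stats::pf(f_stat, df1, df2, lower.tail = FALSE)
                 else NA_real_,
                 sse_shared = sse_shared, sse_free = sse_free)

  if (shared) {
    per <- shared_fit$per_solvent
    out <- list(per_solvent = per, r_enhance = shared_fit$r_enhance,
                r_enhance_ci = shared_fit$r_enhance_ci, shared = TRUE,
                sse = sse_shared, f_test = f_test, weighting = weighting,
                identifiable = shared_fit$identifiable, data = table)
  } else {
    per <- do.call(rbind, lapply(seq_along(solvents), function(i) {
      f <- free_fits[[i]]
      data.frame(solvent = solvents[i], r_o = f$par["r_o"],
                 K_Cl = f$par["K_Cl"],
                 r_o_low = f$ci["r_o", 1], r_o_high = f$ci["r_o", 2],
                 K_Cl_low = f$ci["K_Cl", 1], K_Cl_high = f$ci["K_Cl", 2],
                 r_squared = f$r_squared, row.names = NULL)
    }))
    re <- vapply(free_fits, function(f) unname(f$par["r_enhance"]), 0)
    names(re) <- solvents
    out <- list(per_solvent = per, r_enhance = re, r_enhance_ci = NULL,
                shared = FALSE, sse = sse_free, f_test = f_test,
                weighting = weighting,
                identifiable = all(vapply(free_fits,
                                          function(f) f$identifiable, TRUE)),
                data = table)
  }
  class(out) <- "chloride_fit"
  out
}

# one-solvent Levenberg-Marquardt fit in log-parameter space (enforces
# positivity without active bounds)
single_solvent_fit <- function(cl, k, weighting, conf_level = 0.95) {
  init <- init_single(cl, k)
  resid_fn <- function(lp) {
    p <- exp(lp)
    m <- enhanced_rate(p[1], p[2], p[3], cl)
    if (weighting == "relative") (k - m) / m else (k - m)
  }
  fit <- minpack.lm::nls.lm(
    par = log(pmax(init, 1e-8)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-15, ptol = 1e-15))
  lp <- fit$par
  par <- exp(lp)
  names(par) <- c("r_o", "r_enhance", "K_Cl")
  res <- resid_fn(lp)
  sse <- sum(res^2)
  n <- length(k); p <- 3
  dof <- n - p
  # delta-method covariance on the natural scale
  covm <- matrix(NA_real_, 3, 3)
  identifiable <- TRUE
  if (dof > 0) {
    sigma2 <- sse / dof
    cv_log <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
    if (is.null(cv_log) || any(!is.finite(cv_log))) {
      identifiable <- FALSE
    } else {
      covm <- diag(par) %*% cv_log %*% diag(par)
    }
  }
  # flat data: no curvature, K_Cl unidentifiable -> infinite CI, no error
  rng <- diff(range(k)) / max(mean(k), .Machine$double.eps)
  ci <- wald_ci(par, covm, dof, conf_level)
  rownames(ci) <- names(par)
  if (rng < 1e-8 || !identifiable) {
    identifiable <- FALSE
    ci["K_Cl", ] <- c(0, Inf)
  }
  ci[ci[, 1] < 0, 1] <- 0
  mfit <- enhanced_rate(par[1], par[2], par[3], cl)
  ss_tot <- sum((k - mean(k))^2)
  r2 <- if (ss_tot > 0) 1 - sum((k - mfit)^2) / ss_tot else 0
  list(par = par, ci = ci, sse = sse, r_squared = max(min(r2, 1), 0),
       identifiable = identifiable, fitted = mfit)
}

# pooled fit with one shared log r_enhance and per-solvent log r_o, log K_Cl
global_shared_fit <- function(table, solvents, free_fits, weighting,
                              conf_level = 0.95) {
  ns <- length(solvents)
  idx <- match(table$solvent, solvents)
  cl <- table$cl_M; k <- table$k_obs
  # initialize from the free fits (median enhancement as the shared start)
  re0 <- stats::median(vapply(free_fits,
                              function(f) unname(f$par["r_enhance"]), 0))
  ro0 <- vapply(free_fits, function(f) unname(f$par["r_o"]), 0)
  kc0 <- vapply(free_fits, function(f) unname(f$par["K_Cl"]), 0)
  lp0 <- log(pmax(c(re0, ro0, kc0), 1e-8))
  resid_fn <- function(lp) {
    re <- exp(lp[1])
    ro <- exp(lp[1 + seq_len(ns)])
    kc <- exp(lp[1 + ns + seq_len(ns)])
    m <- enhanced_rate(ro[idx], re, kc[idx], cl)
    if (weighting == "relative") (k - m) / m else (k - m)
  }
  fit <- minpack.lm::nls.lm(
    par = lp0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000,
                                         ftol = 1e-15, ptol = 1e-15))
  lp <- fit$par
  re <- exp(lp[1]); ro <- exp(lp[1 + seq_len(ns)])
  kc <- exp(lp[1 + ns + seq_len(ns)])
  res <- resid_fn(lp)
  sse <- sum(res^2)
  n <- length(k); p <- 2 * ns + 1
  dof <- n - p
  est <- c(re, ro, kc)
  covm <- matrix(NA_real_, p, p)
  identifiable <- TRUE
  if (dof > 0 && sse > 0) {
    sigma2 <- sse / dof
    cv_log <- tryCatch(sigma2 * solve(fit$hessian),
                       error = function(e) NULL)
    if (is.null(cv_log) || any(!is.finite(cv_log))) identifiable <- FALSE
    else covm <- diag(est) %*% cv_log %*% diag(est)
  }
  ci <- wald_ci(est, covm, dof, conf_level)
  ci[ci[, 1] < 0 & is.finite(ci[, 1]), 1] <- 0

  per <- do.call(rbind, lapply(seq_len(ns), function(i) {
    sub <- table$solvent == solvents[i]
    mfit <- enhanced_rate(ro[i], re, kc[i], cl[sub])
    ss_tot <- sum((k[sub] - mean(k[sub]))^2)
    r2 <- if (ss_tot > 0) 1 - sum((k[sub] - mfit)^2) / ss_tot else 0
    data.frame(solvent = solvents[i], r_o = ro[i], K_Cl = kc[i],
               r_o_low = ci[1 + i, 1], r_o_high = ci[1 + i, 2],
               K_Cl_low = ci[1 + ns + i, 1], K_Cl_high = ci[1 + ns + i, 2],
               r_squared = max(min(r2, 1), 0), row.names = NULL)
  }))
  list(per_solvent = per, r_enhance = re,
       r_enhance_ci = ci[1, ], sse = sse, identifiable = identifiable)
}

#' @export
print.chloride_fit <- function(x, ...) {
  cat("<chloride_fit> saturation-enhancement model",
      if (x$shared) "(shared r_enhance)\n" else "(free r_enhance)\n")
  if (x$shared) {
    cat(sprintf("  r_enhance = %.4g", x$r_enhance))
    if (!is.null(x$r_enhance_ci) && all(is.finite(x$r_enhance_ci)))
      cat(sprintf("  [%.4g, %.4g] 95%% CI", x$r_enhance_ci[1],
                  x$r_enhance_ci[2]))
    cat("\n")
  } else {
    cat("  r_enhance per solvent:",
        paste(sprintf("%s: %.3g", names(x$r_enhance), x$r_enhance),
              collapse = ", "), "\n")
  }
  df <- x$per_solvent
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-10s r_o = %.4g  K_Cl = %.4g M^-1  R^2 = %.3f\n",
                df$solvent[i], df$r_o[i], df$K_Cl[i], df$r_squared[i]))
  cat(sprintf("  SSE (%s weighting) = %.4g\n", x$weighting, x$sse))
  if (!is.null(x$f_test) && is.finite(x$f_test$statistic))
    cat(sprintf("  shared-vs-free F(%d,%d) = %.3g, p = %.3g\n",
                x$f_test$df1, x$f_test$df2, x$f_test$statistic,
                x$f_test$p_value))
  if (!x$identifiable)
    cat("  note: K_Cl not identifiable from these data (no curvature)\n")
  invisible(x)
}

#' @export
coef.chloride_fit <- function(object, ...) {
  df <- object$per_solvent
  out <- c(stats::setNames(df$r_o, paste0("r_o.", df$solvent)),
           stats::setNames(df$K_Cl, paste0("K_Cl.", df$solvent)))
  if (object$shared) c(r_enhance = object$r_enhance, out)
  else c(stats::setNames(object$r_enhance,
                         paste0("r_enhance.", names(object$r_enhance))), out)
}

#' @export
predict.chloride_fit <- function(object, newdata = object$data, ...) {
  df <- object$per_solvent
  i <- match(newdata$solvent, df$solvent)
  if (anyNA(i)) stop("unknown solvent in newdata", call. = FALSE)
  re <- if (object$shared) rep(object$r_enhance, nrow(newdata))
        else object$r_enhance[match(newdata$solvent, names(object$r_enhance))]
  enhanced_rate(df$r_o[i], re, df$K_Cl[i], newdata$cl_M)
}

#' @export
plot.chloride_fit <- function(x, ...) {
  d <- x$data
  solv <- unique(d$solvent)
  cols <- seq_along(solv)
  plot(d$cl_M, d$k_obs, log = "y", pch = 16,
       col = cols[match(d$solvent, solv)],
       xlab = "[Cl-] (M)", ylab = "k (M^-1 ks^-1)", ...)
  grid_cl <- seq(min(d$cl_M), max(d$cl_M), length.out = 200)
  for (i in seq_along(solv)) {
    nd <- data.frame(solvent = solv[i], cl_M = grid_cl)
    graphics::lines(grid_cl, predict(x, nd), col = cols[i], lty = 2)
  }
  graphics::legend("bottomright", legend = solv, col = cols, pch = 16,
                   cex = 0.8)
  invisible(x)
}

#' Linear relation between the chloride-free rate constant and K_Cl
#'
#' Ordinary least squares of the chloride-free specific-acid rate constant
#' on the fitted transition-state binding constant across solvent systems.
#' Both quantities grow with the organic co-solvent fraction; their linear
#' relation summarizes that co-variation.
#'
#' @param fit a `chloride_fit` over >= 3 solvents, or a data.frame with
#'   columns `K_Cl` and `k`.
#' @param chloride_free_k optional named vector of measured chloride-free
#'   rate constants per solvent; defaults to the fitted `r_o`.
#' @return an object of class `linear_relation`: `slope`, `intercept`,
#'   `r_squared`, and the underlying `lm` fit.
#' @export
k_vs_kcl_relation <- function(fit, chloride_free_k = NULL) {
  if (inherits(fit, "chloride_fit")) {
    df <- fit$per_solvent
    k <- if (is.null(chloride_free_k)) df$r_o
         else as.numeric(chloride_free_k[match(df$solvent,
                                               names(chloride_free_k))])
    dat <- data.frame(K_Cl = df$K_Cl, k = k)
  } else {
    dat <- as.data.frame(fit)
    stopifnot(all(c("K_Cl", "k") %in% names(dat)))
  }
  if (nrow(dat) < 3)
    stop("need at least 3 solvent systems", call. = FALSE)
  lmfit <- stats::lm(k ~ K_Cl, data = dat)
  ss_tot <- sum((dat$k - mean(dat$k))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(lmfit)^2) / ss_tot else 0
  structure(list(slope = unname(stats::coef(lmfit)[2]),
                 intercept = unname(stats::coef(lmfit)[1]),
                 r_squared = r2, lm = lmfit, data = dat),
            class = "linear_relation")
}

#' @export
print.linear_relation <- function(x, ...) {
  cat(sprintf("<linear_relation> k = %.3g K_Cl %+.3g, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}
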