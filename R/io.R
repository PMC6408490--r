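# Profile CSV dialect and the end-to-end pipeline driver.
#
# One profile per file: a `#`-prefixed key=value header block carrying the
# experimental condition (and optional unit declarations), followed by
# long-format columns time_ks,species,conc_M.  Internal units are always
# M and ks; `time_unit=min` and `conc_unit=mM` headers are converted on
# read.

#' Write a kinetic profile to CSV
#'
#' @param profile a [kinetic_profile()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "kinetic_profile"))
  cond <- profile$condition
  hdr <- c(
    sprintf("# solvent_gvl_massfrac=%.6g", cond$solvent_gvl_massfrac),
    if (!is.na(cond$solvent_name))
      sprintf("# solvent_name=%s", cond$solvent_name),
    sprintf("# acid_name=%s", cond$acid_name),
    sprintf("# acid_conc=%.10g", cond$acid_conc),
    if (!is.na(cond$salt_name)) sprintf("# salt_name=%s", cond$salt_name),
    sprintf("# salt_conc=%.10g", cond$salt_conc),
    sprintf("# anion=%s", cond$anion),
    sprintf("# temperature=%.10g", cond$temperature),
    sprintf("# isotope=%s", cond$isotope)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  kv <- strsplit(kv, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  stats::setNames(vals, vapply(kv, `[[`, "", 1))
}

read_one_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop(sprintf("empty profile file: %s", path), call. = FALSE)
  is_hdr <- grepl("^#", lines)
  hdr <- parse_header(lines[is_hdr])
  body <- lines[!is_hdr]
  if (length(body) < 2)
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  # tolerate unit-suffixed column names declared in the header
  need <- c("time_ks", "species", "conc_M")
  alt <- c(time_ks = "time", conc_M = "conc")
  for (nm in names(alt))
    if (!nm %in% names(df) && alt[[nm]] %in% names(df))
      names(df)[names(df) == alt[[nm]]] <- nm
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$time_ks) | !is.finite(df$conc_M) |
                 !nzchar(df$species))
  if (length(bad) > 0)
    stop(sprintf("%s: malformed data at line(s) %s", path,
                 paste(bad + sum(is_hdr) + 1, collapse = ", ")),
         call. = FALSE)
  # unit normalization
  if (identical(hdr$time_unit, "min")) df$time_ks <- df$time_ks * 60 / 1000
  if (identical(hdr$conc_unit, "mM")) df$conc_M <- df$conc_M / 1000
  num <- function(key, default) {
    if (!is.null(hdr[[key]])) as.numeric(hdr[[key]]) else default
  }
  chr <- function(key, default) {
    if (!is.null(hdr[[key]])) hdr[[key]] else default
  }
  cond <- experiment_condition(
    solvent_gvl_massfrac = num("solvent_gvl_massfrac", 0),
    acid_name = chr("acid_name", "unknown"),
    acid_conc = num("acid_conc", 0),
    salt_name = chr("salt_name", NA_character_),
    salt_conc = num("salt_conc", 0),
    anion = chr("anion", "none"),
    temperature = num("temperature", 373),
    isotope = chr("isotope", "H"),
    solvent_name = hdr$solvent_name)
  wide <- split(df, df$species)
  t <- sort(unique(df$time_ks))
  get_species <- function(nm) {
    if (is.null(wide[[nm]])) return(rep(0, length(t)))
    s <- wide[[nm]][order(wide[[nm]]$time_ks), ]
    if (!isTRUE(all.equal(s$time_ks, t)))
      stop(sprintf("%s: species %s not sampled at every time", path, nm),
           call. = FALSE)
    s$conc_M
  }
  kinetic_profile(cond, t, get_species("reactant"),
                  get_species("primary"), get_species("secondary"))
}

#' Read kinetic profiles from a file or directory
#'
#' @param path a profile CSV, or a directory of them (`*.csv`).
#' @return a list of [kinetic_profile()] objects.
#' @export
read_profiles <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0)
      stop(sprintf("no profile CSVs found in %s", path), call. = FALSE)
  } else {
    if (!file.exists(path))
      stop(sprintf("no such file: %s", path), call. = FALSE)
    files <- path
  }
  lapply(files, read_one_profile)
}

#' Batch-fit rate constants and tabulate the results
#'
#' @param profiles list of [kinetic_profile()] (or a path accepted by
#'   [read_profiles()]).
#' @param ... passed to [fit_rate_constant()].
#' @return data.frame: condition fields plus `k`, `ci_low`, `ci_high`,
#'   `sse`, `n`, `converged`.
#' @export
fit_rate_table <- function(profiles, ...) {
  if (is.character(profiles)) profiles <- read_profiles(profiles)
  rows <- lapply(profiles, function(p) {
    f <- fit_rate_constant(p, ...)
    c0 <- p$condition
    data.frame(solvent_gvl_massfrac = c0$solvent_gvl_massfrac,
               solvent_name = c0$solvent_name,
               acid_name = c0$acid_name, acid_conc = c0$acid_conc,
               salt_name = c0$salt_name, salt_conc = c0$salt_conc,
               anion = c0$anion, temperature = c0$temperature,
               isotope = c0$isotope,
               k = f$k, ci_low = f$ci95[1], ci_high = f$ci95[2],
               sse = f$residual_sse, n = f$n_points,
               converged = f$converged)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing every stochastic stage.
#' @param simulate logical; generate synthetic profiles first.
#' @param profiles path to existing profiles (ignored when `simulate`).
#' @param noise_cv generator noise CV.
#' @param chloride logical; run the chloride-model stage on a synthetic
#'   chloride sweep (or supply `chloride_table`, a CSV with columns
#'   solvent, cl_M, k_obs).
#' @param chloride_table optional path to a chloride table CSV.
#' @param arrhenius logical; run the Arrhenius stage on a synthetic
#'   temperature sweep (or supply `arrhenius_table`, CSV with T_K, k).
#' @param arrhenius_table optional path.
#' @param ci confidence-interval method for rate fits.
#' @param shared share r_enhance in the chloride fit.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("chlorkin_run_"),
                       seed = 1L, simulate = TRUE, profiles = NULL,
                       noise_cv = 0.05, chloride = TRUE,
                       chloride_table = NULL, arrhenius = TRUE,
                       arrhenius_table = NULL, ci = "wald",
                       shared = TRUE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = isTRUE(simulate), profiles = profiles,
              noise_cv = noise_cv, chloride = isTRUE(chloride),
              chloride_table = chloride_table,
              arrhenius = isTRUE(arrhenius),
              arrhenius_table = arrhenius_table,
              ci = ci, shared = isTRUE(shared))
  if (!cfg$simulate && is.null(cfg$profiles))
    stop("either simulate=TRUE or a profiles path is required",
         call. = FALSE)
  if (!is.null(cfg$profiles) && !file.exists(cfg$profiles) &&
      !dir.exists(cfg$profiles))
    stop(sprintf("profiles path does not exist: %s", cfg$profiles),
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[chlorkin:%s] %s", stage, msg))
}

#' Run the analysis pipeline end to end
#'
#' Stages: simulate (optional) -> rate fits -> chloride model ->
#' Arrhenius -> report.  Every stage logs its parameters to stderr; the
#' machine-readable summary (versioned JSON, units in the key names) and
#' a fitted-parameters CSV are written under the output directory.  A
#' rerun with the same config and seed reproduces the summary
#' byte-for-byte.
#'
#' @param config a [run_config()] (or a YAML path).
#' @return the report list, invisibly; written to
#'   `<out_dir>/summary.json` and `<out_dir>/rate_fits.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema_version = "1.0", seed = config$seed)

  # stage: profiles
  if (config$simulate) {
    pipeline_log("simulate", sprintf(
      "generating demo profiles (seed=%d, noise_cv=%g)",
      config$seed, config$noise_cv))
    conds <- list(
      experiment_condition(0.90, "HCl", 0.005),
      experiment_condition(0.90, "H2SO4", 0.005),
      experiment_condition(0, "HCl", 0.5, solvent_name = "water"))
    spec <- generator_spec(conds, true_k = c(62, 20, 0.14),
                           noise_cv = config$noise_cv,
                           seed = config$seed)
    profiles <- lapply(seq_along(conds), function(i)
      simulate_profile(spec, i))
  } else {
    pipeline_log("read", sprintf("reading profiles from %s",
                                 config$profiles))
    profiles <- read_profiles(config$profiles)
  }

  # stage: rate fits
  pipeline_log("fit-rate", sprintf("fitting %d profiles (ci=%s)",
                                   length(profiles), config$ci))
  fits <- tryCatch(fit_rate_table(profiles, ci = config$ci),
                   error = function(e)
                     stop(sprintf("[fit-rate] %s", conditionMessage(e)),
                          call. = FALSE))
  utils::write.csv(fits, file.path(config$out_dir, "rate_fits.csv"),
                   row.names = FALSE)
  report$rate_fits <- lapply(seq_len(nrow(fits)), function(i) list(
    acid = fits$acid_name[i],
    solvent_gvl_massfrac = fits$solvent_gvl_massfrac[i],
    k_M1ks1 = fits$k[i],
    ci95_low_M1ks1 = fits$ci_low[i],
    ci95_high_M1ks1 = fits$ci_high[i],
    converged = fits$converged[i]))

  # stage: chloride model
  if (config$chloride || !is.null(config$chloride_table)) {
    if (!is.null(config$chloride_table)) {
      pipeline_log("fit-chloride", sprintf("reading table %s",
                                           config$chloride_table))
      tab <- utils::read.csv(config$chloride_table,
                             stringsAsFactors = FALSE)
    } else {
      pipeline_log("fit-chloride",
                   "generating synthetic chloride sweep (default design)")
      tab <- generate_chloride_table(chloride_design(),
                                     noise_cv = config$noise_cv,
                                     seed = config$seed)
    }
    cfit <- tryCatch(fit_chloride(tab, shared = config$shared),
                     error = function(e)
                       stop(sprintf("[fit-chloride] %s",
                                    conditionMessage(e)), call. = FALSE))
    report$chloride_model <- list(
      shared = cfit$shared,
      r_enhance = if (cfit$shared) cfit$r_enhance
                  else as.list(cfit$r_enhance),
      per_solvent = lapply(seq_len(nrow(cfit$per_solvent)), function(i)
        list(solvent = cfit$per_solvent$solvent[i],
             r_o_M1ks1 = cfit$per_solvent$r_o[i],
             K_Cl_M1 = cfit$per_solvent$K_Cl[i],
             r_squared = cfit$per_solvent$r_squared[i])),
      sse = cfit$sse)
  } else {
    pipeline_log("fit-chloride", "no chloride series configured; skipped")
    report$chloride_model <- NULL
  }

  # stage: Arrhenius
  if (config$arrhenius || !is.null(config$arrhenius_table)) {
    if (!is.null(config$arrhenius_table)) {
      atab <- utils::read.csv(config$arrhenius_table,
                              stringsAsFactors = FALSE)
      pipeline_log("arrhenius", sprintf("reading table %s",
                                        config$arrhenius_table))
    } else {
      pipeline_log("arrhenius",
                   "generating synthetic temperature sweep (Ea=110)")
      atab <- generate_arrhenius_set(Ea = 110, lnA = 35,
                                     temperatures = seq(363, 403, by = 10),
                                     noise_cv = config$noise_cv,
                                     seed = config$seed)
    }
    afit <- fit_arrhenius(atab)
    report$arrhenius <- list(Ea_kJmol = afit$Ea, lnA = afit$lnA,
                             r_squared = afit$r_squared)
  } else {
    pipeline_log("arrhenius", "no temperature series configured; skipped")
    report$arrhenius <- NULL
  }

  # stage: report
  out_json <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  pipeline_log("report", sprintf("summary written to %s", out_json))
  invisible(report)
}
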