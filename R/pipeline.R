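# End-to-end orchestration: synthesize (or read) -> analyze -> report.

.known_keys <- list(
  top = c("seed", "kinetics", "itc", "saxs", "report"),
  kinetics = c("input", "truth", "noise", "replicates", "weighting"),
  itc = c("input", "protocol", "truth", "noise", "fix_n", "discard_first",
          "fit_baseline", "temperature_K"),
  saxs = c("input", "state", "concentrations", "noise", "k_sf", "monomer_kda"),
  report = c("round", "units"))

.validate_config <- function(config) {
  chk <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  chk(names(config), .known_keys$top, "top level")
  for (sec in c("kinetics", "itc", "saxs", "report"))
    if (!is.null(config[[sec]]))
      chk(names(config[[sec]]), .known_keys[[sec]], sec)
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes the requested assay stages (kinetics, ITC, SAXS) in order from a
#' configuration, either on input files or on synthetic data generated from
#' truth parameters, and assembles a machine-readable report whose blocks
#' mirror the standard result tables (mechanism/Ki/alpha/beta; Kd/dG/dH/-TdS;
#' Rg/Dmax/Vp/MW/state). Identical config and seed give identical reports.
#'
#' @param config a list, or path to a YAML file, with optional sections
#'   `kinetics` (either `input` = kinetics table path, or `truth` = named
#'   truth parameters), `itc` (`input` + `protocol`, or `truth`), `saxs`
#'   (`input` = vector of .dat paths, or `state` = "tetramer"/"octamer";
#'   `monomer_kda` required for classification), a top-level `seed`, and
#'   `report` options. Unknown keys are rejected before any computation.
#' @param out optional path to write the report as JSON.
#' @return list of class `run_report` with per-assay blocks, `provenance`
#'   (seed, package version, timestamp-free config echo) and `warnings`.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  .validate_config(config)
  seed <- config$seed %||% 1L
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  report <- list()

  if (!is.null(config$kinetics)) {
    k <- config$kinetics
    data <- if (!is.null(k$input)) {
      if (!file.exists(k$input)) stop("kinetics input not found: ", k$input)
      read_kinetics_table(k$input)
    } else {
      gen_kinetics_dataset(k$truth, noise = k$noise %||% list(),
                           design = kinetics_design(k$replicates %||% 3),
                           seed = seed)
    }
    fit <- fit_inhibition_global(data, weighting = k$weighting %||% "none")
    if (isTRUE(fit$ambiguous)) note("kinetics: ambiguous mechanism selection")
    if (length(fit$boundary_flags))
      note("kinetics: ", paste(fit$boundary_flags, collapse = ", "))
    p <- as.list(fit$parameters)
    report$kinetics <- list(
      mechanism = fit$mechanism,
      Km_uM = signif(p$Km, 3),
      Ki_uM = if (!is.null(p$Ki)) signif(p$Ki, 2) else NULL,
      alpha = if (!is.null(p$alpha)) signif(p$alpha, 2) else NULL,
      beta = if (!is.null(p$beta)) signif(p$beta, 2) else NULL,
      aicc = as.list(round(fit$criterion, 2)),
      apparent = fit$apparent)
  }

  if (!is.null(config$itc)) {
    it <- config$itc
    titr <- if (!is.null(it$input)) {
      if (!file.exists(it$input)) stop("ITC input not found: ", it$input)
      read_itc_table(it$input, it$protocol)
    } else {
      gen_itc_titration(it$truth, noise = it$noise %||% list(), seed = seed)
    }
    fit <- fit_single_site(titr, fix_n = isTRUE(it$fix_n),
                           discard_first = isTRUE(it$discard_first),
                           fit_baseline = !isFALSE(it$fit_baseline))
    if (length(fit$flags)) note("itc: ", paste(fit$flags, collapse = ", "))
    th <- derive_thermodynamics(fit,
                                temperature_K = it$temperature_K %||% 298.15)
    report$itc <- list(n = round(fit$n, 2),
                       Kd_uM = signif(fit$Kd_uM, 2),
                       dG_kcal_mol = round(th$dG, 1),
                       dH_kcal_mol = round(th$dH, 1),
                       minus_TdS_kcal_mol = round(th$minus_TdS, 1))
  }

  if (!is.null(config$saxs)) {
    sx <- config$saxs
    series <- if (!is.null(sx$input)) {
      missing <- sx$input[!file.exists(sx$input)]
      if (length(missing)) stop("SAXS input not found: ", missing[1])
      lapply(sx$input, read_saxs_dat)
    } else {
      model <- gen_bead_assembly(sx$state %||% "tetramer")
      gen_saxs_series(model,
                      concentrations = sx$concentrations %||% c(1.25, 2.5, 5, 10, 20),
                      noise = sx$noise %||% list(),
                      k_sf = sx$k_sf %||% 0, seed = seed)
    }
    res <- saxs_characterize(series, monomer_kda = sx$monomer_kda)
    if (!res$dmax_satisfied) note("saxs: Dmax decay criterion not met")
    report$saxs <- res[c("Rg_guinier", "Rg_pr", "Dmax", "Vp", "mw_kDa",
                         "state")]
  }

  rep <- structure(list(results = report,
                        provenance = list(seed = seed,
                                          package = "allokin",
                                          version = as.character(
                                            utils::packageVersion("allokin")),
                                          config = config),
                        warnings = warnings_log),
                   class = "run_report")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(rep), out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  rep
}

#' Characterize a SAXS concentration series
#'
#' The full chain used for the tetramer/octamer question: infinite-dilution
#' extrapolation, Guinier fit, Dmax estimation via the regularized p(r),
#' Porod volume and mass estimate, and (when a monomer mass is supplied) the
#' oligomeric-state call.
#'
#' @param series list of [scattering_curve()]s with concentrations (a single
#'   curve is used as-is).
#' @param monomer_kda optional monomer mass for [classify_oligomer()].
#' @return list with `Rg_guinier`, `Rg_pr`, `Dmax`, `Vp`, `mw_kDa`, `state`,
#'   `dmax_satisfied`, plus the underlying `guinier`, `pofr`, `porod`
#'   objects and the merged `curve`.
#' @export
saxs_characterize <- function(series, monomer_kda = NULL) {
  if (inherits(series, "saxs_curve")) series <- list(series)
  curve <- if (length(series) > 1) {
    extrapolate_infinite_dilution(series)
  } else series[[1]]
  gf <- guinier_fit(curve)
  dm <- estimate_dmax(curve)
  pr <- dm$pofr
  po <- porod_volume(curve, guinier = gf)
  state <- if (!is.null(monomer_kda))
    classify_oligomer(po$mw_kDa, monomer_kda)$state else NA_character_
  list(Rg_guinier = gf$Rg, Rg_pr = pr$Rg_pr, Dmax = dm$Dmax,
       Vp = po$Vp, mw_kDa = po$mw_kDa, state = state,
       dmax_satisfied = dm$satisfied,
       guinier = gf, pofr = pr, porod = po, curve = curve)
}

#' @export
print.run_report <- function(x, ...) {
  cat("allokin run report (seed ", x$provenance$seed, ")\n", sep = "")
  for (nm in names(x$results)) {
    cat("== ", nm, " ==\n", sep = "")
    block <- x$results[[nm]]
    for (k in setdiff(names(block), c("apparent", "aicc")))
      cat("  ", k, ": ", paste(format(block[[k]]), collapse = " "), "\n",
          sep = "")
  }
  if (length(x$warnings))
    cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
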