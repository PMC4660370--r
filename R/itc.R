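#' ITC experimental protocol
#'
#' Describes an isothermal titration calorimetry experiment: macromolecule in
#' the cell, ligand in the syringe, the injection schedule and the
#' temperature. The default mirrors a standard small-cell instrument run:
#' 200 uL cell with 20 uM macromolecule titrated with 300 uM ligand by 19
#' injections of 2 uL at 25 C.
#'
#' @param cell_volume_uL active cell volume V0 (uL).
#' @param cell_conc_uM initial macromolecule concentration in the cell (uM).
#' @param syringe_conc_uM ligand concentration in the syringe (uM).
#' @param injection_volumes_uL per-injection volumes (uL); >= 5 injections.
#' @param temperature_C experiment temperature (Celsius).
#' @return list of class `itc_protocol` (adds `temperature_K`).
#' @export
itc_protocol <- function(cell_volume_uL = 200, cell_conc_uM = 20,
                         syringe_conc_uM = 300,
                         injection_volumes_uL = rep(2, 19),
                         temperature_C = 25) {
  .check_pos(cell_volume_uL = cell_volume_uL, cell_conc_uM = cell_conc_uM,
             syringe_conc_uM = syringe_conc_uM)
  if (length(injection_volumes_uL) < 5 || any(injection_volumes_uL <= 0))
    stop("need >= 5 injections with positive volumes")
  structure(list(cell_volume_uL = cell_volume_uL,
                 cell_conc_uM = cell_conc_uM,
                 syringe_conc_uM = syringe_conc_uM,
                 injection_volumes_uL = injection_volumes_uL,
                 temperature_C = temperature_C,
                 temperature_K = temperature_C + 273.15),
            class = "itc_protocol")
}

# Cell concentrations after cumulative injected volume dV (continuous
# displacement model): the cell content is progressively washed out while
# ligand accumulates.
.itc_concentrations <- function(protocol, cum_vol_uL) {
  f <- exp(-cum_vol_uL / protocol$cell_volume_uL)
  list(Mt = protocol$cell_conc_uM * 1e-6 * f,
       Xt = protocol$syringe_conc_uM * 1e-6 * (1 - f))
}

# Fraction of sites occupied at totals Mt, Xt (molar), via the closed-form
# root of the single-site mass-action quadratic theta^2 - a theta + b = 0
# (numerically stable form 2b / (a + sqrt(a^2 - 4b)) avoids cancellation for
# tight binding).
.theta_single_site <- function(Mt, Xt, n, Ka) {
  b <- Xt / (n * Mt)
  a <- 1 + b + 1 / (n * Ka * Mt)
  disc <- a^2 - 4 * b
  if (any(disc < 0)) stop("negative discriminant in single-site model; ",
                          "check protocol and parameters")
  2 * b / (a + sqrt(disc))
}

#' Expected per-injection heats for a single-site binding model
#'
#' Computes the heat evolved at each injection of an ITC titration for `n`
#' identical independent sites with association constant `Ka` and molar
#' binding enthalpy `dH`. After each injection the equilibrium bound-ligand
#' content of the cell is obtained from the mass-action quadratic; the
#' per-injection heat is the difference in total heat content between
#' consecutive states with the standard displacement (perfusion) correction
#' \deqn{\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}}
#' Cumulative heat saturates at `n * Mt * V0 * dH` as the ligand goes to
#' excess.
#'
#' @param protocol an [itc_protocol()].
#' @param n binding stoichiometry (sites per macromolecule), > 0.
#' @param Ka association constant (1/M), > 0.
#' @param dH molar binding enthalpy (kcal/mol).
#' @return numeric vector of per-injection heats in ucal.
#' @seealso [fit_single_site()], [gen_itc_titration()]
#' @export
single_site_heats <- function(protocol, n, Ka, dH) {
  stopifnot(inherits(protocol, "itc_protocol"))
  .check_pos(n = n, Ka = Ka)
  if (!is.finite(dH)) stop("dH must be finite")
  V0_L <- protocol$cell_volume_uL * 1e-6
  cum <- cumsum(protocol$injection_volumes_uL)
  conc <- .itc_concentrations(protocol, c(0, cum))
  theta <- c(0, .theta_single_site(conc$Mt[-1], conc$Xt[-1], n, Ka))
  # total heat content (ucal) of the cell at each state
  Q <- n * theta * conc$Mt * V0_L * dH * 1e9
  dV <- protocol$injection_volumes_uL
  i <- seq_along(dV) + 1L
  Q[i] - Q[i - 1L] + (dV / protocol$cell_volume_uL) * (Q[i] + Q[i - 1L]) / 2
}

#' Assemble an ITC titration
#'
#' @param protocol an [itc_protocol()].
#' @param heats integrated per-injection heats (ucal).
#' @return list of class `itc_titration` with `protocol`, `heats` and
#'   `molar_ratios` (total ligand over total macromolecule after each
#'   injection).
#' @export
itc_titration <- function(protocol, heats) {
  stopifnot(inherits(protocol, "itc_protocol"),
            length(heats) == length(protocol$injection_volumes_uL),
            all(is.finite(heats)))
  conc <- .itc_concentrations(protocol, cumsum(protocol$injection_volumes_uL))
  structure(list(protocol = protocol, heats = as.numeric(heats),
                 molar_ratios = conc$Xt / conc$Mt),
            class = "itc_titration")
}

#' Fit the single-site binding model to an ITC titration
#'
#' Least-squares fit of stoichiometry `n`, dissociation constant `Kd`
#' (through `Ka = 1/Kd`), enthalpy `dH` and a constant per-injection baseline
#' offset (dilution heat) to integrated injection heats. The association
#' constant is fitted on the log scale.
#'
#' The information content of an isotherm is governed by the Wiseman
#' parameter `c = n * Mt * Ka`; outside roughly [1, 1000] the shape
#' constrains the parameters weakly. A fit with `c` outside [0.01, 1e6] is
#' flagged `low_information`; at low `c` it is standard practice to fix
#' `n = 1` (`fix_n = TRUE`). A titration with essentially zero heats leaves
#' `Kd` unidentifiable and is flagged `unidentifiable` with `dH ~ 0`.
#'
#' @param titration an [itc_titration()].
#' @param fix_n fix the stoichiometry at `n = 1` instead of fitting it.
#' @param discard_first drop the first injection (common practice for the
#'   diffusion-compromised first injection) instead of relying on the fitted
#'   baseline offset.
#' @param fit_baseline fit a constant per-injection dilution-heat offset
#'   (default TRUE). Set FALSE when no dilution-heat component is expected
#'   (e.g. blank-subtracted or synthetic data): at low Wiseman `c` the
#'   offset is nearly collinear with (Kd, dH) and fitting it needlessly
#'   degrades the binding parameters.
#' @return list of class `binding_fit` with `n`, `Kd_uM`, `dH`,
#'   `baseline_offset`, `se` (named vector), `c_wiseman`, `flags`, `rss`,
#'   and the `nls` object (`fit`).
#' @export
fit_single_site <- function(titration, fix_n = FALSE, discard_first = FALSE,
                            fit_baseline = TRUE) {
  stopifnot(inherits(titration, "itc_titration"))
  protocol <- titration$protocol
  heats <- titration$heats
  keep <- seq_along(heats)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 5) stop("need >= 5 usable injections")

  flags <- character(0)
  V0_L <- protocol$cell_volume_uL * 1e-6
  scale_ucal <- protocol$cell_conc_uM * 1e-6 * V0_L * 1e9  # ucal per kcal/mol
  if (max(abs(heats)) < 1e-6 * scale_ucal) {
    return(structure(list(n = if (fix_n) 1 else NA_real_, Kd_uM = NA_real_,
                          dH = 0, baseline_offset = mean(heats),
                          se = c(n = NA, logKa = NA, dH = NA, offset = NA),
                          c_wiseman = NA_real_,
                          flags = c("unidentifiable", "zero_heats"),
                          rss = sum((heats - mean(heats))^2), fit = NULL),
                     class = "binding_fit"))
  }

  y <- heats[keep]
  model_fun <- function(n, logKa, dH, offset) {
    single_site_heats(protocol, n, exp(logKa), dH)[keep] + offset
  }
  moles_first <- protocol$injection_volumes_uL[1] * 1e-6 *
    protocol$syringe_conc_uM * 1e-6
  dH0 <- heats[1] / (moles_first * 1e9)           # stoichiometric-limit guess
  starts_logKa <- log(c(1e4, 1e5, 1e6, 1e7))  # Ka multistart grid (1/M)
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)
  best <- NULL
  for (lk in starts_logKa) {
    fit <- tryCatch({
      if (fix_n && !fit_baseline)
        minpack.lm::nlsLM(y ~ model_fun(1, logKa, dH, 0),
                          start = list(logKa = lk, dH = dH0), control = ctl)
      else if (fix_n)
        minpack.lm::nlsLM(y ~ model_fun(1, logKa, dH, offset),
                          start = list(logKa = lk, dH = dH0, offset = 0),
                          control = ctl)
      else if (!fit_baseline)
        minpack.lm::nlsLM(y ~ model_fun(n, logKa, dH, 0),
                          start = list(n = 1, logKa = lk, dH = dH0),
                          lower = c(1e-3, log(1e-2), -Inf),
                          control = ctl)
      else
        minpack.lm::nlsLM(y ~ model_fun(n, logKa, dH, offset),
                          start = list(n = 1, logKa = lk, dH = dH0, offset = 0),
                          lower = c(1e-3, log(1e-2), -Inf, -Inf),
                          control = ctl)
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("single-site fit failed from all starting values")
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  n_fit <- if (fix_n) 1 else unname(cf["n"])
  Ka <- exp(unname(cf["logKa"]))
  Kd_uM <- 1 / Ka * 1e6
  cw <- n_fit * protocol$cell_conc_uM * 1e-6 * Ka
  if (cw < 0.01 || cw > 1e6) flags <- c(flags, "low_information")

  # delta-method SE for Kd (uM) from SE of logKa
  se_Kd <- if (!is.na(se["logKa"])) Kd_uM * se[["logKa"]] else NA_real_
  se_out <- c(n = if (fix_n) 0 else unname(se["n"]),
              logKa = unname(se["logKa"]), Kd_uM = se_Kd,
              dH = unname(se["dH"]),
              offset = if (fit_baseline) unname(se["offset"]) else 0)
  structure(list(n = n_fit, Kd_uM = Kd_uM, dH = unname(cf["dH"]),
                 baseline_offset = if (fit_baseline) unname(cf["offset"]) else 0,
                 se = se_out, c_wiseman = cw, flags = flags,
                 rss = best$rss, fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Single-site ITC fit\n")
  cat(sprintf("  n      = %.3f\n  Kd     = %.3g uM\n  dH     = %.2f kcal/mol\n",
              x$n, x$Kd_uM, x$dH))
  cat(sprintf("  offset = %.3g ucal   Wiseman c = %.3g\n",
              x$baseline_offset, x$c_wiseman))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Thermodynamic decomposition of a binding constant
#'
#' Computes the binding free energy `dG = R T ln(Kd)` (Kd in molar,
#' `R = 1.9872e-3 kcal/mol/K`) and the entropic term `-TdS = dG - dH`, so the
#' identity `dG = dH + (-TdS)` holds exactly.
#'
#' @param Kd_uM dissociation constant in uM (> 0), or a `binding_fit`.
#' @param dH binding enthalpy (kcal/mol); taken from the fit if one is given.
#' @param temperature_K temperature in K (default 298.15).
#' @return list with `dG`, `dH`, `minus_TdS` (kcal/mol) and `temperature_K`.
#' @examples
#' derive_thermodynamics(1.7, dH = -26.4)  # dG = -7.9, -TdS = 18.5 (1 d.p.)
#' @export
derive_thermodynamics <- function(Kd_uM, dH = NULL, temperature_K = 298.15) {
  if (inherits(Kd_uM, "binding_fit")) {
    if (is.null(dH)) dH <- Kd_uM$dH
    Kd_uM <- Kd_uM$Kd_uM
  }
  .check_pos(Kd_uM = Kd_uM, temperature_K = temperature_K)
  if (is.null(dH) || !is.finite(dH)) stop("dH must be supplied and finite")
  R <- 1.9872e-3
  dG <- R * temperature_K * log(Kd_uM * 1e-6)
  list(dG = dG, dH = dH, minus_TdS = dG - dH, temperature_K = temperature_K)
}
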