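# Seeded generators emulating the three experimental designs. Every
# generator is a pure function of (truth, design, seed): the RNG state is
# saved and restored around each call.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else rm(".Random.seed", envir = .GlobalEnv))
  }
  force(expr)
}

#' Default kinetics assay design
#'
#' The substrate grid is a 2-fold dilution series from 5000 uM down to about
#' 19.5 uM (9 levels of IMP at fixed 0.5 mM NAD+), inhibitor at zero plus
#' five log-spaced levels spanning 20 to 5000 uM, three replicates.
#'
#' @param replicates replicates per (S, I) condition.
#' @return list with `S`, `I`, `replicates`.
#' @export
kinetics_design <- function(replicates = 3) {
  list(S = 5000 / 2^(8:0),
       I = c(0, exp(seq(log(20), log(5000), length.out = 5))),
       replicates = replicates)
}

#' Generate a synthetic inhibition-kinetics dataset
#'
#' Evaluates the requested rate law on the design grid and perturbs each
#' velocity as `v * (1 + N(0, proportional_sd)) + N(0, additive_sd)`.
#' Deterministic for a given seed. Velocities can go slightly negative at
#' near-zero rates through the additive noise; they are flagged by
#' [kinetic_dataset()], not clipped.
#'
#' @param truth list with `mechanism` and parameters `Vmax`, `Km`, and as
#'   required `Ki`, `alpha`, `beta`.
#' @param noise list with `proportional_sd` (default 0.02) and `additive_sd`
#'   (default `0.002 * Vmax`, a small instrument floor).
#' @param design a [kinetics_design()].
#' @param seed RNG seed.
#' @param inhibitor_id,enzyme_id labels passed to [kinetic_dataset()].
#' @return a [kinetic_dataset()].
#' @export
gen_kinetics_dataset <- function(truth, noise = list(), design = kinetics_design(),
                                 seed = NULL, inhibitor_id = "inhibitor",
                                 enzyme_id = "enzyme") {
  prop <- if (is.null(noise$proportional_sd)) 0.02 else noise$proportional_sd
  addv <- if (is.null(noise$additive_sd)) 0.002 * truth$Vmax else noise$additive_sd
  .check_nonneg(proportional_sd = prop, additive_sd = addv)
  grid <- expand.grid(substrate = design$S, inhibitor = design$I,
                      replicate = seq_len(design$replicates))
  v_true <- predict_velocity(grid$substrate, grid$inhibitor,
                             Vmax = truth$Vmax, Km = truth$Km, Ki = truth$Ki,
                             alpha = truth$alpha, beta = truth$beta,
                             mechanism = truth$mechanism)
  v <- .with_seed(seed, {
    v_true * (1 + stats::rnorm(length(v_true), 0, prop)) +
      stats::rnorm(length(v_true), 0, addv)
  })
  kinetic_dataset(grid$substrate, grid$inhibitor, v, grid$replicate,
                  inhibitor_id = inhibitor_id, enzyme_id = enzyme_id)
}

#' Generate a synthetic absorbance progress curve
#'
#' Produces an A340 trace whose product formation approaches saturation
#' exponentially (initial slope = the true initial velocity), for testing
#' initial-velocity extraction.
#'
#' @param v0 true initial velocity (uM/min).
#' @param duration_s trace length (s).
#' @param dt_s sampling interval (s).
#' @param tau_s exponential-approach time constant (s); `Inf` gives a
#'   perfectly linear trace.
#' @param noise_sd Gaussian absorbance noise (A units).
#' @param A0 starting absorbance.
#' @param extinction_coeff,path_length Beer-Lambert constants.
#' @param seed RNG seed.
#' @return data.frame with `time_s`, `A340`; attribute `v0_true`.
#' @export
gen_time_course <- function(v0, duration_s = 300, dt_s = 5, tau_s = Inf,
                            noise_sd = 0, A0 = 0.05,
                            extinction_coeff = 6220, path_length = 1,
                            seed = NULL) {
  t <- seq(0, duration_s, by = dt_s)
  t_min <- t / 60
  P_uM <- if (is.finite(tau_s)) {
    tau_min <- tau_s / 60
    v0 * tau_min * (1 - exp(-t_min / tau_min))
  } else v0 * t_min
  A <- A0 + P_uM * 1e-6 * extinction_coeff * path_length
  A <- .with_seed(seed, A + stats::rnorm(length(A), 0, noise_sd))
  out <- data.frame(time_s = t, A340 = A)
  attr(out, "v0_true") <- v0
  out
}

#' Generate a synthetic ITC titration
#'
#' Computes the single-site heats for the truth parameters on the protocol
#' and adds Gaussian noise scaled to the titration's own heat scale: the
#' noise standard deviation is `proportional_sd` (default 2 percent) times
#' the largest expected injection-heat magnitude.
#'
#' @param truth list with `n`, `Kd_uM`, `dH` (kcal/mol).
#' @param noise list with `proportional_sd` (default 0.02) and optional
#'   `additive_sd_ucal`.
#' @param protocol an [itc_protocol()].
#' @param seed RNG seed.
#' @return an [itc_titration()]; attribute `truth` carries the generating
#'   parameters.
#' @export
gen_itc_titration <- function(truth, noise = list(),
                              protocol = itc_protocol(), seed = NULL) {
  prop <- if (is.null(noise$proportional_sd)) 0.02 else noise$proportional_sd
  addv <- if (is.null(noise$additive_sd_ucal)) 0 else noise$additive_sd_ucal
  .check_nonneg(proportional_sd = prop, additive_sd_ucal = addv)
  Ka <- 1 / (truth$Kd_uM * 1e-6)
  h <- single_site_heats(protocol, truth$n, Ka, truth$dH)
  href <- max(abs(h))  # heat scale of this titration
  hn <- .with_seed(seed, {
    h + stats::rnorm(length(h), 0, prop * href) +
      if (addv > 0) stats::rnorm(length(h), 0, addv) else 0
  })
  out <- itc_titration(protocol, hn)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic SAXS concentration series
#'
#' Computes the Debye profile of a bead model on the default beamline-like
#' grid (q from 0.005 to 0.35 1/A, 400 points), scales it by each
#' concentration, optionally applies a low-q interparticle structure-factor
#' attenuation `(1 - k_sf * c * exp(-(q/q_sf)^2))`, and adds Gaussian noise
#' with a Poisson-like sigma profile `sigma(q) = s0 sqrt(I(q) + floor)`,
#' where `s0` is set so the relative error at the lowest q equals
#' `proportional_sd`.
#'
#' @param model a [bead_model()].
#' @param concentrations mg/mL values (default the 1.25-20 dilution series).
#' @param noise list with `proportional_sd` (default 0.01).
#' @param k_sf interparticle structure-factor strength per (mg/mL)
#'   (default 0 = ideal dilution).
#' @param q_sf structure-factor decay scale (1/A).
#' @param q q grid.
#' @param seed RNG seed.
#' @return list of [scattering_curve()]s with concentration attributes.
#' @export
gen_saxs_series <- function(model, concentrations = c(1.25, 2.5, 5, 10, 20),
                            noise = list(), k_sf = 0, q_sf = 0.02,
                            q = seq(0.005, 0.35, length.out = 400),
                            seed = NULL) {
  prop <- if (is.null(noise$proportional_sd)) 0.01 else noise$proportional_sd
  .check_nonneg(proportional_sd = prop)
  base <- debye_profile(model, q)
  .with_seed(seed, {
    lapply(concentrations, function(cc) {
      I <- cc * base$I * (1 - k_sf * cc * exp(-(q / q_sf)^2))
      if (prop == 0) {
        # noiseless: nominal uniform sigma keeps downstream weighting sane
        return(scattering_curve(q, I, sigma = rep(1e-9 * max(I), length(q)),
                                concentration = cc))
      }
      s0 <- prop * sqrt(max(I[1], .Machine$double.xmin))
      sigma <- s0 * sqrt(pmax(I, 0) + 1e-6 * max(I))
      In <- I + stats::rnorm(length(I), 0, sigma)
      scattering_curve(q, In, sigma = sigma, concentration = cc)
    })
  })
}
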