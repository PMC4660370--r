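#' Construct a kinetic dataset
#'
#' Bundles initial-velocity observations over a (substrate, inhibitor) grid
#' for one enzyme/inhibitor pair, with validation. Velocities that are
#' negative (possible through measurement noise at near-zero rates) are
#' retained but flagged in an attribute, never silently clipped.
#'
#' @param substrate substrate concentrations (uM, e.g. IMP).
#' @param inhibitor inhibitor concentrations (uM).
#' @param velocity initial velocities (uM/min by convention).
#' @param replicate integer replicate index (default 1).
#' @param inhibitor_id label for the inhibitor (e.g. "GMP", "GDP", "GTP",
#'   "none").
#' @param enzyme_id label for the enzyme.
#' @param velocity_units unit label carried along in reports.
#' @return data.frame of class `kinetic_dataset` with columns `substrate`,
#'   `inhibitor`, `velocity`, `replicate`; attributes `enzyme_id`,
#'   `inhibitor_id`, `velocity_units`, `negative_velocity_rows`.
#' @export
kinetic_dataset <- function(substrate, inhibitor, velocity, replicate = 1L,
                            inhibitor_id = "inhibitor", enzyme_id = "enzyme",
                            velocity_units = "uM/min") {
  n <- length(velocity)
  stopifnot(length(substrate) == n, length(inhibitor) == n)
  if (any(substrate < 0) || any(inhibitor < 0))
    stop("concentrations must be >= 0")
  if (length(unique(substrate)) < 5)
    stop("need >= 5 distinct substrate levels")
  if (!any(inhibitor == 0))
    stop("dataset must contain an inhibitor-free control series")
  d <- data.frame(substrate = as.numeric(substrate),
                  inhibitor = as.numeric(inhibitor),
                  velocity = as.numeric(velocity),
                  replicate = rep_len(as.integer(replicate), n))
  attr(d, "enzyme_id") <- enzyme_id
  attr(d, "inhibitor_id") <- inhibitor_id
  attr(d, "velocity_units") <- velocity_units
  attr(d, "negative_velocity_rows") <- which(d$velocity < 0)
  class(d) <- c("kinetic_dataset", "data.frame")
  d
}

#' Initial velocity from an absorbance time course
#'
#' Estimates the initial reaction velocity from an A340 progress curve
#' (NAD+ -> NADH turnover) by linear regression over the longest initial
#' window that is still linear, then converts the slope to uM/min via
#' Beer-Lambert (A = epsilon * c * l).
#'
#' The window is the longest prefix of the trace with at least `min_points`
#' points whose linear fit has R^2 >= `r2_min` and no systematic residual
#' trend (runs test, p > 0.01) -- substrate-depletion curvature produces a
#' sign trend in the residuals long before it degrades R^2. A perfectly
#' flat trace is accepted as zero rate.
#'
#' @param times time points in seconds, strictly increasing.
#' @param absorbance A340 readings.
#' @param extinction_coeff molar extinction coefficient (1/M/cm); default the
#'   standard NADH value 6220.
#' @param path_length cuvette path length in cm.
#' @param r2_min linearity threshold for the window search.
#' @param min_points minimum number of points in the window.
#' @return list with `v0` (uM/min), `slope_A_per_min`, `window` (index range
#'   used), `r2`, and `n_points`.
#' @examples
#' t <- seq(0, 300, by = 10)
#' a <- 0.05 + 0.00622 / 60 * t          # 0.00622 A/min -> 1 uM/min
#' estimate_initial_velocity(t, a)$v0
#' @export
estimate_initial_velocity <- function(times, absorbance,
                                      extinction_coeff = 6220,
                                      path_length = 1,
                                      r2_min = 0.995, min_points = 5) {
  stopifnot(length(times) == length(absorbance))
  if (length(times) < min_points)
    stop("need at least ", min_points, " time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  .check_pos(extinction_coeff = extinction_coeff, path_length = path_length)

  n <- length(times)
  best <- NULL
  for (k in n:min_points) {
    tt <- times[1:k]; aa <- absorbance[1:k]
    fit <- stats::lm(aa ~ tt)
    res <- stats::residuals(fit)
    ssres <- sum(res^2)
    sstot <- sum((aa - mean(aa))^2)
    # a flat (or exactly linear) trace has ~zero residual variance: linear
    degenerate <- ssres < .Machine$double.eps * max(1, mean(aa)^2) * k
    r2 <- if (sstot < .Machine$double.eps * max(1, mean(aa)^2) * k) 1
          else 1 - ssres / sstot
    if (r2 >= r2_min && (degenerate || .runs_test_p(res) > 0.01)) {
      best <- list(fit = fit, k = k, r2 = r2)
      break
    }
  }
  if (is.null(best))
    stop("no initial window of >= ", min_points,
         " points passes the linearity check (R^2 >= ", r2_min, ")")
  slope_per_s <- unname(stats::coef(best$fit)[2])
  slope_A_min <- slope_per_s * 60
  v0 <- slope_A_min / (extinction_coeff * path_length) * 1e6  # M/min -> uM/min
  list(v0 = v0, slope_A_per_min = slope_A_min,
       window = c(1L, best$k), r2 = best$r2, n_points = best$k)
}

#' Fit the Michaelis-Menten equation to one velocity series
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)` for a single
#' inhibitor level, with automatic initial guesses (`Vmax = 1.1 * max(v)`,
#' `Km` = substrate level where `v` is nearest half-maximal).
#'
#' @param S substrate concentrations (>= 5 distinct levels).
#' @param v velocities.
#' @param weights optional least-squares weights (e.g. `1/v^2`).
#' @return list of class `mm_fit` with `Vmax`, `Km`, their standard errors
#'   (`se`), `rss`, `n` and the underlying `nls` object (`fit`).
#' @export
fit_michaelis_menten <- function(S, v, weights = NULL) {
  stopifnot(length(S) == length(v))
  if (length(unique(S)) < 5) stop("need >= 5 distinct substrate levels")
  start <- list(Vmax = 1.1 * max(v), Km = S[which.min(abs(v - max(v) / 2))])
  if (start$Km <= 0) start$Km <- stats::median(S[S > 0])
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), start = start,
                      lower = c(Vmax = 1e-12, Km = 1e-12),
                      weights = if (is.null(weights)) rep(1, length(v)) else weights,
                      control = ctl),
    error = function(e)
      stop("Michaelis-Menten fit failed to converge (starts: Vmax=",
           signif(start$Vmax, 4), ", Km=", signif(start$Km, 4), "): ",
           conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 2))
  structure(list(Vmax = unname(cf["Vmax"]), Km = unname(cf["Km"]),
                 se = c(Vmax = unname(se[1]), Km = unname(se[2])),
                 rss = sum(stats::residuals(fit)^2), n = length(v), fit = fit),
            class = "mm_fit")
}

# AICc from a least-squares fit; k counts mean-model parameters (sigma added
# here).
.aicc_ls <- function(rss, n, k_mean) {
  k <- k_mean + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Global inhibition fit with mechanism classification
#'
#' Fits the full (substrate, inhibitor) velocity grid simultaneously to the
#' three candidate rate laws -- no inhibition, competitive, and partial
#' (hyperbolic) mixed-type -- by weighted nonlinear least squares, then
#' selects the mechanism by corrected Akaike information criterion (AICc).
#' Per-inhibitor-level Michaelis-Menten fits are retained as diagnostics and
#' reported as apparent parameters.
#'
#' Starting values: `Vmax = 1.1 * max(v)`; `Km` = substrate level nearest
#' half-maximal velocity; `Ki` = median nonzero inhibitor level; `alpha = 2`;
#' `beta = 0.5`. Bounds: all parameters > 0, `alpha` in (1e-2, 1e6],
#' `beta` in [0, 10]. Parameters pinned at the `alpha` upper or `beta` lower
#' bound are reported via the `boundary_flags` element rather than silently
#' accepted.
#'
#' @param data a [kinetic_dataset()] (or data.frame with columns `substrate`,
#'   `inhibitor`, `velocity`).
#' @param weighting `"none"` (default; ordinary least squares) or `"inv_v2"`
#'   (weights `1/v^2`, relative error model).
#' @param delta_aicc indifference threshold: if the best mechanism beats a
#'   simpler one by less than this AICc difference, the simpler one is
#'   selected and `ambiguous = TRUE` is set.
#' @return object of class `inhibition_fit`: list with `mechanism`,
#'   `parameters` (named vector), `se`, `criterion` (AICc per candidate),
#'   `ambiguous`, `boundary_flags`, `apparent` (per-level Vmax_app/Km_app
#'   from sequential MM fits), `fits` (the three nls objects), `n`.
#' @seealso [predict_velocity()], [classify_mechanism()], [hanes_woolf()]
#' @export
fit_inhibition_global <- function(data, weighting = c("none", "inv_v2"),
                                  delta_aicc = 2) {
  weighting <- match.arg(weighting)
  d <- as.data.frame(data)
  stopifnot(all(c("substrate", "inhibitor", "velocity") %in% names(d)))
  ilev <- sort(unique(d$inhibitor))
  if (length(ilev[ilev > 0]) < 2 || !0 %in% ilev)
    stop("need a control series plus >= 2 nonzero inhibitor levels")

  S <- d$substrate; I <- d$inhibitor; v <- d$velocity
  w <- if (weighting == "inv_v2") 1 / pmax(v, 1e-8)^2 else rep(1, length(v))
  start_mm <- list(Vmax = 1.1 * max(v), Km = S[which.min(abs(v - max(v) / 2))])
  if (start_mm$Km <= 0) start_mm$Km <- stats::median(S[S > 0])
  Ki0 <- stats::median(I[I > 0])
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)

  # anchor the starting (Vmax, Km) on the inhibitor-free control series: the
  # no-inhibition fit can pin Km at its bound on strongly inhibited data
  mm0 <- fit_michaelis_menten(d$substrate[d$inhibitor == 0],
                              d$velocity[d$inhibitor == 0])
  st0 <- list(Vmax = mm0$Vmax, Km = max(mm0$Km, 1e-6))

  # try several starting points, keep the best converged solution
  try_nls <- function(formula, starts, lower, upper = NULL) {
    best <- NULL
    for (st in starts) {
      fit <- tryCatch({
        if (is.null(upper))
          minpack.lm::nlsLM(formula, start = st, lower = lower, weights = w,
                            control = ctl)
        else
          minpack.lm::nlsLM(formula, start = st, lower = lower, upper = upper,
                            weights = w, control = ctl)
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(w * stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
    if (is.null(best))
      stop("global fit failed to converge from all starting points",
           call. = FALSE)
    best$fit
  }

  fits <- list()
  fits$none <- try_nls(v ~ Vmax * S / (Km + S),
                       list(start_mm, st0), lower = c(1e-12, 1e-12))
  fits$competitive <- try_nls(
    v ~ Vmax * S / (Km * (1 + I / Ki) + S),
    list(c(st0, list(Ki = Ki0)), c(st0, list(Ki = Ki0 / 10)),
         c(st0, list(Ki = Ki0 * 10))),
    lower = c(1e-12, 1e-12, 1e-12))
  stc <- stats::coef(fits$competitive)
  Kic <- max(stc[["Ki"]], 1e-6)
  fits$mixed <- try_nls(
    v ~ Vmax * (1 + beta * I / (alpha * Ki)) * S /
      (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki))),
    lapply(list(c(2, 0.5), c(5, 0.1), c(1.5, 0.8), c(10, 0.02)),
           function(ab) list(Vmax = st0$Vmax, Km = st0$Km, Ki = Kic,
                             alpha = ab[1], beta = ab[2])),
    lower = c(1e-12, 1e-12, 1e-12, 1e-2, 0),
    upper = c(Inf, Inf, Inf, 1e6, 10))

  n <- length(v)
  kpar <- c(none = 2, competitive = 3, mixed = 5)
  crit <- vapply(names(fits), function(m) {
    .aicc_ls(sum(w * stats::residuals(fits[[m]])^2), n, kpar[[m]])
  }, numeric(1))

  sel <- classify_mechanism(crit, delta_aicc = delta_aicc)
  best <- fits[[sel$mechanism]]
  cf <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))),
                 error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)

  boundary <- character(0)
  if (sel$mechanism == "mixed") {
    if (cf[["alpha"]] > 1e6 * 0.99) boundary <- c(boundary, "alpha_at_upper_bound")
    if (cf[["beta"]] < 1e-10) boundary <- c(boundary, "beta_at_zero_bound")
  }

  apparent <- do.call(rbind, lapply(ilev, function(ic) {
    di <- d[d$inhibitor == ic, ]
    mm <- tryCatch(fit_michaelis_menten(di$substrate, di$velocity),
                   error = function(e) NULL)
    if (is.null(mm))
      return(data.frame(I = ic, Vmax_app = NA_real_, Km_app = NA_real_))
    data.frame(I = ic, Vmax_app = mm$Vmax, Km_app = mm$Km)
  }))

  structure(list(mechanism = sel$mechanism,
                 parameters = cf, se = se, criterion = crit,
                 ambiguous = sel$ambiguous, boundary_flags = boundary,
                 apparent = apparent, fits = fits, n = n,
                 enzyme_id = attr(data, "enzyme_id"),
                 inhibitor_id = attr(data, "inhibitor_id")),
            class = "inhibition_fit")
}

#' Select the inhibition mechanism from per-candidate criterion values
#'
#' Chooses the candidate mechanism with the lowest AICc; when the winner beats
#' a simpler candidate (fewer parameters) by less than `delta_aicc`, the
#' simpler mechanism is returned and the ambiguity flag is set. The candidate
#' complexity order is none < competitive < mixed. Deterministic given the
#' criterion values.
#'
#' @param criterion named numeric vector of AICc values with names `none`,
#'   `competitive`, `mixed`; an [fit_inhibition_global()] object is also
#'   accepted (its `criterion` element is used).
#' @param delta_aicc indifference threshold (default 2).
#' @return list with `mechanism` and logical `ambiguous`.
#' @export
classify_mechanism <- function(criterion, delta_aicc = 2) {
  if (inherits(criterion, "inhibition_fit")) criterion <- criterion$criterion
  order_simple <- c("none", "competitive", "mixed")
  stopifnot(all(order_simple %in% names(criterion)))
  crit <- criterion[order_simple]
  best <- order_simple[which.min(crit)]
  ambiguous <- FALSE
  # walk from the simplest candidate: adopt the first one within delta_aicc
  # of the winner
  for (m in order_simple) {
    if (m == best) break
    if (crit[[m]] - crit[[best]] < delta_aicc) {
      best <- m
      ambiguous <- TRUE
      break
    }
  }
  list(mechanism = best, ambiguous = ambiguous)
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("Global inhibition fit (", x$n, " observations)\n", sep = "")
  cat("  mechanism: ", x$mechanism,
      if (isTRUE(x$ambiguous)) "  [ambiguous: simpler model within delta-AICc]",
      "\n", sep = "")
  p <- x$parameters; s <- x$se
  for (nm in names(p))
    cat(sprintf("  %-6s %12.5g  (se %.3g)\n", nm, p[[nm]], s[[nm]]))
  cat("  AICc:", paste(sprintf("%s=%.2f", names(x$criterion), x$criterion),
                       collapse = "  "), "\n")
  if (length(x$boundary_flags))
    cat("  boundary flags:", paste(x$boundary_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Hanes-Woolf linearization per inhibitor level
#'
#' Transforms each inhibitor level's series to (S, S/v) and fits a straight
#' line per level. For data obeying the rate law, the slope equals
#' `1/Vmax_app` and the intercept `Km_app/Vmax_app`; a competitive inhibitor
#' gives lines parallel to the control, a mixed-type inhibitor changes the
#' slope by the factor `(1 + I/(alpha Ki)) / (1 + beta I/(alpha Ki))`.
#' Zero or negative velocities are excluded from the transform (recorded in
#' `excluded`). A slope-equality F statistic across levels (interaction test
#' of the `S:level` term) is included as the parallelism diagnostic.
#'
#' @param data a [kinetic_dataset()] or compatible data.frame.
#' @return list of class `hanes_woolf` with `lines` (data.frame: I, slope,
#'   intercept, n), `points` (S, S_over_v, I), `excluded` (row indices),
#'   `slope_test` (list F, df, p_value) and `skipped_levels`.
#' @export
hanes_woolf <- function(data) {
  d <- as.data.frame(data)
  stopifnot(all(c("substrate", "inhibitor", "velocity") %in% names(d)))
  usable <- d$velocity > 0 & d$substrate > 0
  excluded <- which(!usable)
  du <- d[usable, ]
  du$S_over_v <- du$substrate / du$velocity
  lev <- sort(unique(d$inhibitor))
  lines <- list(); skipped <- numeric(0)
  for (ic in lev) {
    di <- du[du$inhibitor == ic, ]
    if (nrow(di) < 3) {
      warning("Hanes-Woolf: fewer than 3 usable points at I = ", ic,
              "; level skipped")
      skipped <- c(skipped, ic)
      next
    }
    fit <- stats::lm(S_over_v ~ substrate, data = di)
    cf <- stats::coef(fit)
    lines[[length(lines) + 1L]] <-
      data.frame(I = ic, slope = unname(cf[2]), intercept = unname(cf[1]),
                 n = nrow(di))
  }
  lines <- do.call(rbind, lines)

  slope_test <- NULL
  keep <- !(du$inhibitor %in% skipped)
  if (length(unique(du$inhibitor[keep])) >= 2) {
    dk <- du[keep, ]
    dk$level <- factor(dk$inhibitor)
    full <- stats::lm(S_over_v ~ substrate * level, data = dk)
    parallel <- stats::lm(S_over_v ~ substrate + level, data = dk)
    an <- stats::anova(parallel, full)
    slope_test <- list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                       p_value = an$`Pr(>F)`[2])
  }
  structure(list(lines = lines,
                 points = du[, c("substrate", "S_over_v", "inhibitor")],
                 excluded = excluded, slope_test = slope_test,
                 skipped_levels = skipped),
            class = "hanes_woolf")
}
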