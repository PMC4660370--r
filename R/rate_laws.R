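#' Enzyme velocity under Michaelis-Menten and inhibition rate laws
#'
#' Evaluates the initial-velocity rate law for an enzyme obeying
#' Michaelis-Menten kinetics, optionally inhibited by a compound acting either
#' competitively or by the partial (hyperbolic) mixed-type mechanism.
#'
#' The three model forms are
#' \describe{
#'   \item{`none`}{\eqn{v = V_{max} S / (K_m + S)}}
#'   \item{`competitive`}{\eqn{v = V_{max} S / (K_m (1 + I/K_i) + S)}}
#'   \item{`mixed`}{\eqn{v = V_{max} (1 + \beta I/(\alpha K_i)) S /
#'     [K_m (1 + I/K_i) + S (1 + I/(\alpha K_i))]}}
#' }
#' where \eqn{\alpha} quantifies the heterotropic substrate-inhibitor
#' interaction (\eqn{\alpha = 1}: independent binding; \eqn{\alpha \to \infty}:
#' purely competitive) and \eqn{\beta} the fractional activity of the ternary
#' enzyme-substrate-inhibitor complex (\eqn{\beta = 0}: dead-end complex;
#' \eqn{\beta < 1}: partial inhibition). At `I = 0` all mechanisms reduce to
#' the Michaelis-Menten rate; for the mixed form the limit
#' \eqn{I \to \infty} is \eqn{\beta V_{max} S / (\alpha K_m + S)}.
#'
#' @param S substrate concentration(s), same units as `Km` (conventionally uM).
#' @param I inhibitor concentration(s), same units as `Ki`. Recycled against
#'   `S`.
#' @param Vmax maximal velocity (rate units, e.g. uM/min). Must be > 0.
#' @param Km Michaelis constant (> 0).
#' @param Ki inhibition constant (> 0); required unless `mechanism = "none"`.
#' @param alpha heterotropic interaction factor (> 0); mixed mechanism only.
#' @param beta fractional ternary-complex activity (>= 0); mixed mechanism
#'   only.
#' @param mechanism one of `"none"`, `"competitive"`, `"mixed"`.
#' @return numeric vector of velocities (same units as `Vmax`).
#' @examples
#' predict_velocity(51, 0, Vmax = 1, Km = 51)                      # Vmax/2
#' predict_velocity(51, 210, Vmax = 1, Km = 51, Ki = 210, alpha = 6.5,
#'                  beta = 0.033, mechanism = "mixed")
#' @seealso [apparent_parameters()], [fit_inhibition_global()]
#' @export
predict_velocity <- function(S, I = 0, Vmax, Km, Ki = NULL,
                             alpha = NULL, beta = NULL,
                             mechanism = c("none", "competitive", "mixed")) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(S), is.numeric(I))
  if (any(S < 0) || any(I < 0))
    stop("substrate and inhibitor concentrations must be >= 0")
  .check_pos(Vmax = Vmax, Km = Km)
  n <- max(length(S), length(I))
  S <- rep_len(S, n); I <- rep_len(I, n)
  switch(mechanism,
    none = Vmax * S / (Km + S),
    competitive = {
      .check_pos(Ki = Ki)
      Vmax * S / (Km * (1 + I / Ki) + S)
    },
    mixed = {
      .check_pos(Ki = Ki, alpha = alpha)
      .check_nonneg(beta = beta)
      Vmax * (1 + beta * I / (alpha * Ki)) * S /
        (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki)))
    })
}

#' Apparent Michaelis-Menten parameters at a given inhibitor concentration
#'
#' For the competitive and mixed mechanisms the rate law at fixed inhibitor
#' concentration `I` is exactly Michaelis-Menten with apparent parameters
#' \deqn{V_{max}^{app} = V_{max}\frac{1 + \beta I/(\alpha K_i)}
#'   {1 + I/(\alpha K_i)}, \qquad
#'   K_m^{app} = K_m\frac{1 + I/K_i}{1 + I/(\alpha K_i)}}
#' (competitive: \eqn{V_{max}^{app} = V_{max}},
#' \eqn{K_m^{app} = K_m(1 + I/K_i)}). `Vmax_app` decreases monotonically from
#' `Vmax` at `I = 0` toward `beta * Vmax` as `I` grows (for `beta < 1`), and
#' `Km_app(0) = Km`.
#'
#' @param I inhibitor concentration(s).
#' @param fit an [fit_inhibition_global()] result, or a plain list with
#'   elements `mechanism`, `Vmax`, `Km` and (as required) `Ki`, `alpha`,
#'   `beta`.
#' @return data.frame with columns `I`, `Vmax_app`, `Km_app`.
#' @examples
#' p <- list(mechanism = "competitive", Vmax = 1, Km = 51, Ki = 600)
#' apparent_parameters(c(0, 600), p)   # Km doubles at I = Ki
#' @export
apparent_parameters <- function(I, fit) {
  stopifnot(is.numeric(I), all(I >= 0))
  p <- .as_param_list(fit)
  out <- switch(p$mechanism,
    none = data.frame(I = I, Vmax_app = rep(p$Vmax, length(I)),
                      Km_app = rep(p$Km, length(I))),
    competitive = {
      .check_pos(Ki = p$Ki)
      data.frame(I = I, Vmax_app = rep(p$Vmax, length(I)),
                 Km_app = p$Km * (1 + I / p$Ki))
    },
    mixed = {
      .check_pos(Ki = p$Ki, alpha = p$alpha)
      .check_nonneg(beta = p$beta)
      u <- I / (p$alpha * p$Ki)
      data.frame(I = I,
                 Vmax_app = p$Vmax * (1 + p$beta * u) / (1 + u),
                 Km_app = p$Km * (1 + I / p$Ki) / (1 + u))
    },
    stop("unknown mechanism: ", p$mechanism))
  out
}

.as_param_list <- function(fit) {
  if (inherits(fit, "inhibition_fit"))
    return(c(list(mechanism = fit$mechanism), as.list(fit$parameters)))
  stopifnot(is.list(fit), !is.null(fit$mechanism))
  fit
}

.check_pos <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (is.null(x) || !is.numeric(x) || !all(is.finite(x)) || any(x <= 0))
      stop("parameter '", nm, "' must be finite and > 0", call. = FALSE)
  }
  invisible(TRUE)
}

.check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (is.null(x) || !is.numeric(x) || !all(is.finite(x)) || any(x < 0))
      stop("parameter '", nm, "' must be finite and >= 0", call. = FALSE)
  }
  invisible(TRUE)
}
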