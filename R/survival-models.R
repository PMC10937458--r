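#' Natural-log cell survival under each model
#'
#' `ln_survival()` evaluates ln of the surviving fraction at dose `d` (Gy) for
#' a parameter object built by one of the [survival_params] constructors.
#' `survival_fraction()` is `exp(ln_survival(...))`.
#'
#' The model forms are:
#' \describe{
#'   \item{LQ}{\eqn{\ln S = -(\alpha d + \beta d^2)}}
#'   \item{USC}{LQ for \eqn{d \le D_T}; \eqn{\ln S = -(d - D_q)/D_0} for
#'     \eqn{d \ge D_T} (multi-target tail).}
#'   \item{LQL}{LQ for \eqn{d \le D_T};
#'     \eqn{\ln S = -(\alpha D_T + \beta D_T^2 + \gamma (d - D_T))} above,
#'     with \eqn{\gamma = \alpha + 2 \beta D_T} so the join is C1.}
#'   \item{PLQ}{\eqn{\ln S = -(\alpha d + \beta d^2)/(1 + \gamma d)}, the Pade
#'     expansion of LQ; reduces to LQ at \eqn{\gamma = 0}.}
#' }
#'
#' @param params A `survival_params` object.
#' @param d Vector of doses in Gy, all `>= 0`. For PLQ the denominator
#'   `1 + gamma * d` must stay positive.
#' @return Numeric vector of ln surviving fractions (`<= 0`).
#' @examples
#' p <- usc_params_scc()
#' ln_survival(p, c(0, 2, 4.6628, 20))
#' survival_fraction(p, 2)
#' @export
ln_survival <- function(params, d) {
  UseMethod("ln_survival")
}

check_dose_vec <- function(d) {
  stop_if(!is.numeric(d) || any(!is.finite(d)), "'d' must be finite numeric")
  stop_if(any(d < 0), "negative dose is not allowed")
  as.numeric(d)
}

#' @export
ln_survival.survival_params_lq <- function(params, d) {
  d <- check_dose_vec(d)
  -(params$alpha * d + params$beta * d^2)
}

#' @export
ln_survival.survival_params_usc <- function(params, d) {
  d <- check_dose_vec(d)
  ifelse(d <= params$DT,
         -(params$alpha * d + params$beta * d^2),
         -(d - params$Dq) / params$D0)
}

#' @export
ln_survival.survival_params_lql <- function(params, d) {
  d <- check_dose_vec(d)
  lnS_T <- -(params$alpha * params$DT + params$beta * params$DT^2)
  ifelse(d <= params$DT,
         -(params$alpha * d + params$beta * d^2),
         lnS_T - params$gamma * (d - params$DT))
}

#' @export
ln_survival.survival_params_plq <- function(params, d) {
  d <- check_dose_vec(d)
  denom <- 1 + params$gamma * d
  stop_if(any(denom <= 0), "PLQ denominator 1 + gamma*d must be positive")
  -(params$alpha * d + params$beta * d^2) / denom
}

#' @rdname ln_survival
#' @export
survival_fraction <- function(params, d) exp(ln_survival(params, d))
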