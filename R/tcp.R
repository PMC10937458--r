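#' Logistic TCP model parameters
#'
#' Container for the dose-response parameters of the EUD-based tumor control
#' probability model: `TCD50`, the uniform dose giving 50% control; `gamma50`,
#' the normalized slope of the response curve at `TCD50`; and `a`, the
#' tissue-specific gEUD volume-effect exponent (negative for tumors, so cold
#' spots dominate). Defaults are the photon-derived squamous-cell-carcinoma
#' values TCD50 = 46.8 Gy, gamma50 = 2.0, a = -13; the published TCD50
#' standard uncertainty (6.4 Gy) is stored for reference but not propagated.
#'
#' @param TCD50 Dose with 50% control probability (Gy), `> 0`.
#' @param gamma50 Normalized slope at TCD50, `> 0`.
#' @param a gEUD exponent, nonzero.
#' @param TCD50_uncertainty Recorded uncertainty of TCD50 (Gy).
#' @return A classed list `tcp_params`.
#' @examples
#' tcp_params()
#' @export
tcp_params <- function(TCD50 = 46.8, gamma50 = 2.0, a = -13,
                       TCD50_uncertainty = 6.4) {
  TCD50 <- check_num(TCD50, "TCD50", 0, strict = TRUE)
  gamma50 <- check_num(gamma50, "gamma50", 0, strict = TRUE)
  a <- check_num(a, "a")
  stop_if(a == 0, "'a' must be nonzero")
  structure(list(TCD50 = TCD50, gamma50 = gamma50, a = a,
                 TCD50_uncertainty = TCD50_uncertainty),
            class = "tcp_params")
}

#' @export
print.tcp_params <- function(x, ...) {
  cat(sprintf("<TCP parameters: TCD50 = %.4g +/- %.2g Gy, gamma50 = %.3g, a = %.4g>\n",
              x$TCD50, x$TCD50_uncertainty, x$gamma50, x$a))
  invisible(x)
}

#' Generalized equivalent uniform dose of a DVH
#'
#' Niemierko's power-mean reduction of a non-uniform dose distribution,
#' \deqn{gEUD = \left(\sum_i v_i D_i^{a}\right)^{1/a},}
#' computed in log space for numerical stability (with `a = -13`, doses are
#' raised to large negative powers; the naive sum underflows for realistic
#' dose levels). The equal-volume form is the special case `v_i = 1/N`. For
#' tumors `a` is negative, so the gEUD is dominated by the coldest part of
#' the distribution; `a = 1` gives the mean dose.
#'
#' @param x A [dvh] object (converted to differential internally).
#' @param a Volume-effect exponent, nonzero (default -13, squamous cell
#'   carcinoma).
#' @return gEUD in the dose unit of `x`; always within
#'   `[min_dose(x), max_dose(x)]`.
#' @examples
#' h <- dvh(c(40, 60), c(0.5, 0.5), unit = "Gy")
#' geud(h)          # 42.17 Gy: far below the 50 Gy mean
#' geud(h, a = 1)   # mean dose
#' @export
geud <- function(x, a = -13) {
  stopifnot(inherits(x, "dvh"))
  a <- check_num(a, "a")
  stop_if(a == 0, "'a' must be nonzero")
  d <- to_differential(x)
  keep <- d$volume > 0
  dose <- d$dose[keep]
  vol <- d$volume[keep]
  stop_if(a < 0 && any(dose <= 1e-6),
          "gEUD with a < 0 diverges for (near-)zero dose bins; found dose <= 1e-6")
  # log-sum-exp over log(v_i) + a*log(D_i)
  lt <- log(vol) + a * log(dose)
  m <- max(lt)
  exp((m + log(sum(exp(lt - m)))) / a)
}

#' Logistic tumor control probability
#'
#' `tcp_uniform()` evaluates the logistic dose-response model for a uniform
#' dose `D`:
#' \deqn{TCP(D) = \frac{100}{1 + (TCD_{50}/D)^{4\gamma_{50}}} \; [\%].}
#' `tcp_from_geud()` is the same curve evaluated at the gEUD of a non-uniform
#' distribution, which is how TCP is reported for BNCT targets. `tcp_dvh()`
#' composes [geud()] with `tcp_from_geud()`.
#'
#' @param D Uniform dose in Gy (EQD2 scale), `> 0`. Vectorized.
#' @param gEUD Generalized equivalent uniform dose in Gy, `> 0`. Vectorized.
#' @param params A [tcp_params()] object.
#' @return TCP in percent (0-100), full precision; round only for reporting.
#' @examples
#' tcp_uniform(46.8)        # 50% by definition of TCD50
#' tcp_from_geud(80.7)      # 98.7%
#' @export
tcp_uniform <- function(D, params = tcp_params()) {
  stop_if(!is.numeric(D) || any(!is.finite(D)) || any(D <= 0),
          "'D' must be positive and finite")
  100 / (1 + (params$TCD50 / D)^(4 * params$gamma50))
}

#' @rdname tcp_uniform
#' @export
tcp_from_geud <- function(gEUD, params = tcp_params()) {
  stop_if(!is.numeric(gEUD) || any(!is.finite(gEUD)) || any(gEUD <= 0),
          "'gEUD' must be positive and finite")
  tcp_uniform(gEUD, params)
}

#' @rdname tcp_uniform
#' @param x A [dvh] in EQD2 (Gy).
#' @export
tcp_dvh <- function(x, params = tcp_params()) {
  tcp_from_geud(geud(x, a = params$a), params)
}

#' Classify a TCP value against clinical response levels
#'
#' Maps TCP (percent) to the response levels observed to correspond to RECIST
#' categories for recurrent head-and-neck cancer treated with BNCT:
#' TCP >= 60% is complete-response level, TCP >= 25% partial-response level,
#' anything lower sub-PR (stable/progressive disease territory). Boundaries
#' are inclusive.
#'
#' @param tcp_percent TCP in percent, within `[0, 100]`. Vectorized.
#' @return Factor with levels `"sub-PR" < "PR-level" < "CR-level"`.
#' @examples
#' classify_response(c(95.5, 30.8, 4.4))
#' @export
classify_response <- function(tcp_percent) {
  stop_if(!is.numeric(tcp_percent) || any(!is.finite(tcp_percent)) ||
            any(tcp_percent < 0) || any(tcp_percent > 100),
          "'tcp_percent' must lie in [0, 100]")
  lab <- ifelse(tcp_percent >= 60, "CR-level",
                ifelse(tcp_percent >= 25, "PR-level", "sub-PR"))
  factor(lab, levels = c("sub-PR", "PR-level", "CR-level"), ordered = TRUE)
}
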