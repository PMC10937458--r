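#' Parameter containers for cell-survival models
#'
#' Constructors for the four cell-survival parameterizations used throughout
#' the package: linear quadratic (LQ), universal survival curve (USC), linear
#' quadratic linear (LQL) and Pade linear quadratic (PLQ). Each constructor
#' validates the model-specific invariants and returns a classed list that the
#' generic [ln_survival()] dispatches on.
#'
#' The USC model joins an LQ branch at low dose to a multi-target linear
#' branch (slope -1/D0, extrapolation intercept Dq) at high dose. Requiring
#' the two branches to agree in value and slope at the transition dose forces
#'
#' \deqn{D_T = 2 D_q / (1 - \alpha D_0), \qquad
#'       \beta = (1 - \alpha D_0)^2 / (4 D_q D_0).}
#'
#' `survival_params_usc()` derives `beta` and `DT` from these relations when
#' they are not supplied, and when they are supplied checks that `DT` matches
#' the smooth-join value to a relative tolerance of `1e-3` and that the two
#' branch formulas for ln-survival agree at `DT` to the same relative
#' tolerance.
#'
#' @param alpha Linear coefficient (1/Gy), `>= 0`.
#' @param beta Quadratic coefficient (1/Gy^2), `>= 0`. Derived from the
#'   smooth-join constraint when `NULL` (USC only).
#' @param D0 Reciprocal slope of the multi-target branch (Gy), `> 0`.
#' @param Dq Extrapolation intercept of the multi-target branch (Gy), `> 0`.
#' @param DT Transition dose (Gy). Derived when `NULL` (USC, from the
#'   smooth-join relation); required for LQL.
#' @param gamma High-dose slope (1/Gy). For LQL it must equal
#'   `alpha + 2 * beta * DT` (derived when `NULL`); for PLQ it is the free
#'   Pade denominator coefficient, `>= 0`.
#'
#' @return An object of class `c("survival_params_<kind>", "survival_params")`
#'   with fields as listed above plus `kind`.
#'
#' @examples
#' p <- survival_params_usc(alpha = 0.2111, D0 = 0.9603, Dq = 1.8588)
#' p$DT   # smooth-join transition dose
#' ln_survival(p, c(2, 10))
#' @name survival_params
NULL

new_survival_params <- function(kind, fields) {
  structure(c(fields, list(kind = kind)),
            class = c(paste0("survival_params_", kind), "survival_params"))
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_num <- function(x, name, lower = -Inf, strict = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("'%s' must be a single finite number", name))
  bad <- if (strict) x <= lower else x < lower
  stop_if(bad, sprintf("'%s' must be %s %g (got %g)", name,
                       if (strict) ">" else ">=", lower, x))
  as.numeric(x)
}

#' @rdname survival_params
#' @export
survival_params_lq <- function(alpha, beta) {
  alpha <- check_num(alpha, "alpha", 0)
  beta <- check_num(beta, "beta", 0)
  stop_if(alpha == 0 && beta == 0, "'alpha' and 'beta' cannot both be zero")
  new_survival_params("lq", list(alpha = alpha, beta = beta))
}

#' Transition dose of the universal survival curve
#'
#' Closed-form transition dose at which the LQ branch joins the multi-target
#' branch with matched value and slope: `2 * Dq / (1 - alpha * D0)`.
#'
#' @param alpha Linear LQ coefficient (1/Gy).
#' @param D0 Reciprocal slope of the multi-target branch (Gy).
#' @param Dq Extrapolation intercept of the multi-target branch (Gy).
#' @return Transition dose in Gy.
#' @examples
#' usc_transition_dose(0.2111, 0.9603, 1.8588)  # 4.6628 Gy
#' @export
usc_transition_dose <- function(alpha, D0, Dq) {
  alpha <- check_num(alpha, "alpha", 0)
  D0 <- check_num(D0, "D0", 0, strict = TRUE)
  Dq <- check_num(Dq, "Dq", 0, strict = TRUE)
  stop_if(alpha * D0 >= 1,
          sprintf("no valid transition dose: alpha * D0 = %g >= 1", alpha * D0))
  2 * Dq / (1 - alpha * D0)
}

#' @rdname survival_params
#' @export
survival_params_usc <- function(alpha, beta = NULL, D0, Dq, DT = NULL) {
  alpha <- check_num(alpha, "alpha", 0, strict = TRUE)
  D0 <- check_num(D0, "D0", 0, strict = TRUE)
  Dq <- check_num(Dq, "Dq", 0, strict = TRUE)
  stop_if(alpha * D0 >= 1, sprintf("invalid USC parameters: alpha * D0 = %g >= 1",
                                   alpha * D0))
  DT_join <- usc_transition_dose(alpha, D0, Dq)
  beta_join <- (1 - alpha * D0)^2 / (4 * Dq * D0)
  if (is.null(beta)) beta <- beta_join else beta <- check_num(beta, "beta", 0, strict = TRUE)
  if (is.null(DT)) {
    DT <- DT_join
  } else {
    DT <- check_num(DT, "DT", 0, strict = TRUE)
    stop_if(abs(DT - DT_join) > 1e-3 * DT_join,
            sprintf("DT = %g is inconsistent with the smooth-join value 2*Dq/(1 - alpha*D0) = %g",
                    DT, DT_join))
  }
  p <- new_survival_params("usc", list(alpha = alpha, beta = beta,
                                       D0 = D0, Dq = Dq, DT = DT))
  lnS_lq <- -(alpha * DT + beta * DT^2)
  lnS_mt <- -(DT - Dq) / D0
  stop_if(abs(lnS_lq - lnS_mt) > 1e-3 * abs(lnS_lq),
          sprintf("ln-survival discontinuous at DT: LQ branch %g vs multi-target branch %g",
                  lnS_lq, lnS_mt))
  p
}

#' @rdname survival_params
#' @export
survival_params_lql <- function(alpha, beta, DT, gamma = NULL) {
  alpha <- check_num(alpha, "alpha", 0)
  beta <- check_num(beta, "beta", 0)
  DT <- check_num(DT, "DT", 0, strict = TRUE)
  gamma_lq <- alpha + 2 * beta * DT
  if (is.null(gamma)) {
    gamma <- gamma_lq
  } else {
    gamma <- check_num(gamma, "gamma", 0)
    stop_if(abs(gamma - gamma_lq) > 1e-9,
            sprintf("gamma = %g must equal the LQ slope at DT, alpha + 2*beta*DT = %g",
                    gamma, gamma_lq))
  }
  new_survival_params("lql", list(alpha = alpha, beta = beta,
                                  DT = DT, gamma = gamma))
}

#' @rdname survival_params
#' @export
survival_params_plq <- function(alpha, beta, gamma) {
  alpha <- check_num(alpha, "alpha", 0)
  beta <- check_num(beta, "beta", 0)
  gamma <- check_num(gamma, "gamma", 0)
  new_survival_params("plq", list(alpha = alpha, beta = beta, gamma = gamma))
}

#' Reference USC coefficients for squamous cell carcinoma
#'
#' Published universal-survival-curve coefficients for head-and-neck squamous
#' cell carcinoma (FaDu line): alpha = 0.2111 /Gy, beta = 0.0890 /Gy^2,
#' D0 = 0.9603 Gy, Dq = 1.8588 Gy, DT = 4.6628 Gy. These are the defaults for
#' all dose-conversion and pipeline functions.
#'
#' @return A `survival_params_usc` object.
#' @examples
#' usc_params_scc()$DT
#' @export
usc_params_scc <- function() {
  survival_params_usc(alpha = 0.2111, beta = 0.0890,
                      D0 = 0.9603, Dq = 1.8588, DT = 4.6628)
}

n_free_params <- function(kind) {
  switch(kind, lq = 2L, usc = 3L, lql = 3L, plq = 3L,
         stop("unknown model kind: ", kind))
}

#' @export
print.survival_params <- function(x, ...) {
  cat(sprintf("<%s survival parameters>\n", toupper(x$kind)))
  flds <- setdiff(names(x), "kind")
  for (f in flds) cat(sprintf("  %-6s %.6g\n", f, x[[f]]))
  invisible(x)
}
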