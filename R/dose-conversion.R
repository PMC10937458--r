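#' RBE/CBE weighting factors and the weighted BNCT dose
#'
#' The weighted dose (Gy-w) of a BNCT field is the sum of its physical dose
#' components, each multiplied by a biological weighting factor: the boron
#' capture dose by the compound biological effectiveness (CBE) of BPA, the
#' thermal and fast neutron doses by the neutron relative biological
#' effectiveness (RBE), and the photon dose by a gamma weight. Conventional
#' values are RBE 3.2 for neutrons, CBE 3.8 for tumor / 1.3 for normal tissue
#' with BPA, and 1.0 for gamma.
#'
#' @param rbe_neutron Neutron RBE (default 3.2).
#' @param cbe_boron Boron compound CBE (default 3.8, tumor; use 1.3 for
#'   normal tissue).
#' @param gamma_weight Photon weighting factor (default 1.0).
#' @return `weighting_factors()` returns a classed list;
#'   `weighted_dose()` a scalar dose in Gy-w.
#' @examples
#' weighted_dose(boron = 2, thermal = 0.5, fast = 0.5, gamma = 1)  # 11.8 Gy-w
#' @export
weighting_factors <- function(rbe_neutron = 3.2, cbe_boron = 3.8,
                              gamma_weight = 1.0) {
  structure(list(rbe_neutron = check_num(rbe_neutron, "rbe_neutron", 0, TRUE),
                 cbe_boron = check_num(cbe_boron, "cbe_boron", 0, TRUE),
                 gamma_weight = check_num(gamma_weight, "gamma_weight", 0, TRUE)),
            class = "weighting_factors")
}

#' @rdname weighting_factors
#' @param boron,thermal,fast,gamma Physical dose components in Gy, each
#'   `>= 0`: boron capture, thermal neutron, fast neutron, photon.
#' @param factors A [weighting_factors()] object.
#' @export
weighted_dose <- function(boron = 0, thermal = 0, fast = 0, gamma = 0,
                          factors = weighting_factors()) {
  for (nm in c("boron", "thermal", "fast", "gamma")) {
    check_num(get(nm), nm, 0)
  }
  factors$cbe_boron * boron +
    factors$rbe_neutron * (thermal + fast) +
    factors$gamma_weight * gamma
}

new_bed <- function(bed, alpha, branch) {
  structure(list(bed = bed, effect_E = alpha * bed, branch = branch),
            class = "bed_result")
}

#' @export
print.bed_result <- function(x, ...) {
  cat(sprintf("BED %.4f Gy (E = %.4f, %s branch)\n",
              x$bed, x$effect_E, x$branch))
  invisible(x)
}

#' Biologically effective dose under the universal survival curve
#'
#' `bed_fractionated()` evaluates the USC form of the BED for `n` identical
#' fractions of size `d`:
#' \deqn{BED = n d (1 + d \beta/\alpha)} for \eqn{d \le D_T} (LQ branch) and
#' \deqn{BED = (n d - n D_q)/(\alpha D_0)} for \eqn{d \ge D_T}
#' (multi-target branch).
#'
#' `bed_bnct()` is the single high-dose delivery specialization used for a
#' BNCT weighted dose \eqn{D_{BNCT}} (usually above the transition dose):
#' \deqn{BED = (D_{BNCT} - D_q)/(\alpha D_0).}
#' A dose between \eqn{D_q} and \eqn{D_T} still follows the multi-target line
#' (with a warning); a dose below \eqn{D_q} would give a negative BED and is
#' an error.
#'
#' @param n Number of fractions, integer `>= 1`.
#' @param d Dose per fraction in Gy (Gy-w for BNCT), `> 0`.
#' @param params A `survival_params_usc` object (default [usc_params_scc()]).
#' @return A `bed_result`: list with `bed` (Gy), `effect_E` (`alpha * bed`),
#'   and the `branch` used (`"LQ"` or `"multi-target"`).
#' @examples
#' bed_fractionated(n = 1, d = 2)         # LQ branch
#' bed_bnct(20)                           # single 20 Gy-w delivery
#' @export
bed_fractionated <- function(n, d, params = usc_params_scc()) {
  stopifnot(inherits(params, "survival_params_usc"))
  stop_if(!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n),
          "'n' must be a positive integer")
  d <- check_num(d, "d", 0, strict = TRUE)
  if (d <= params$DT) {
    new_bed(n * d * (1 + d * params$beta / params$alpha), params$alpha, "LQ")
  } else {
    new_bed((n * d - n * params$Dq) / (params$alpha * params$D0),
            params$alpha, "multi-target")
  }
}

#' @rdname bed_fractionated
#' @param D_bnct Single-delivery weighted dose in Gy-w, `>= Dq`.
#' @export
bed_bnct <- function(D_bnct, params = usc_params_scc()) {
  stopifnot(inherits(params, "survival_params_usc"))
  D_bnct <- check_num(D_bnct, "D_bnct", 0)
  stop_if(D_bnct < params$Dq,
          sprintf("D_bnct = %g Gy-w is below Dq = %g Gy: negative BED on the multi-target line",
                  D_bnct, params$Dq))
  if (D_bnct < params$DT) {
    warning(sprintf(paste0("D_bnct = %g Gy-w is below the transition dose DT = %g Gy; ",
                           "the single-delivery BED formula assumes the multi-target ",
                           "branch and is applied as stated"),
                    D_bnct, params$DT), call. = FALSE)
  }
  new_bed((D_bnct - params$Dq) / (params$alpha * params$D0),
          params$alpha, "multi-target")
}

#' Equivalent dose in 2-Gy fractions for a BNCT delivery
#'
#' Converts a single high-dose BNCT weighted dose into the total dose that,
#' delivered in conventional 2-Gy photon fractions, produces the same
#' biologically effective dose under the USC model. When 2 Gy lies on the LQ
#' branch (2 <= DT, true for the squamous-cell defaults) this is
#' \deqn{EQD_2 = \frac{BED_{BNCT}}{1 + 2\beta/\alpha}
#'            = \frac{(D_{BNCT} - D_q)/(\alpha D_0)}{1 + 2\beta/\alpha}.}
#' In the opposite (rarely reachable) regime 2 >= DT both sides sit on the
#' multi-target line and \eqn{EQD_2 = D_{BNCT} + (n - 1) D_q} with `n` the
#' smallest whole number of 2-Gy fractions covering the result, resolved by
#' fixed-point iteration; the returned value then carries attribute
#' `branch = "multi-target"`.
#'
#' @inheritParams bed_fractionated
#' @param D_bnct Single-delivery weighted dose in Gy-w, `>= Dq`.
#' @return EQD2 in Gy (attribute `branch` records the 2-Gy branch used).
#' @examples
#' eqd2_from_bnct(18.5)   # 44.53 Gy
#' eqd2_from_bnct(20)     # 48.54 Gy
#' @export
eqd2_from_bnct <- function(D_bnct, params = usc_params_scc()) {
  stopifnot(inherits(params, "survival_params_usc"))
  bed <- bed_bnct(D_bnct, params)$bed
  if (2 <= params$DT) {
    structure(bed / (1 + 2 * params$beta / params$alpha), branch = "LQ")
  } else {
    # both deliveries on the multi-target line; n fixed by n*2 >= EQD2
    n <- max(1, ceiling(D_bnct / 2))
    repeat {
      e <- D_bnct + (n - 1) * params$Dq
      n_new <- max(1, ceiling(e / 2))
      if (n_new == n) break
      n <- n_new
    }
    structure(e, branch = "multi-target")
  }
}

#' Convert a weighted-dose DVH to an EQD2 DVH
#'
#' Maps every bin dose of a Gy-w DVH through the BNCT isoeffect conversion,
#' leaving volumes untouched. With `fractions > 1` each bin dose is read as a
#' per-fraction dose delivered identically `fractions` times: the per-bin BED
#' is `(n*d - n*Dq)/(alpha*D0)` before the 2-Gy isoeffect division. Any bin
#' dose below `Dq` is an error naming the bin — no silent clamping.
#'
#' @param x A [dvh] in weighted dose (Gy-w); either kind.
#' @param params A `survival_params_usc` object.
#' @param fractions Number of identical fractions (integer `>= 1`, default 1).
#' @return A [dvh] of the same kind with unit `"Gy"` (EQD2).
#' @examples
#' h <- dvh(c(18.5, 25.3), c(0.5, 0.5))
#' eqd2_dvh(h)$dose
#' @export
eqd2_dvh <- function(x, params = usc_params_scc(), fractions = 1L) {
  stopifnot(inherits(x, "dvh"), inherits(params, "survival_params_usc"))
  stop_if(!is.numeric(fractions) || length(fractions) != 1L ||
            fractions < 1 || fractions != round(fractions),
          "'fractions' must be a positive integer")
  bad <- which(x$dose < params$Dq)
  stop_if(length(bad) > 0L,
          sprintf("bin %d (dose %g %s) is below Dq = %g Gy; cannot convert",
                  bad[[1L]], x$dose[[bad[[1L]]]], x$unit, params$Dq))
  if (any(x$dose < params$DT)) {
    warning(sprintf(paste0("%d bin(s) below the transition dose DT = %g Gy ",
                           "follow the multi-target line as stated"),
                    sum(x$dose < params$DT), params$DT), call. = FALSE)
  }
  stop_if(2 > params$DT,
          "per-bin conversion requires 2 Gy on the LQ branch (2 <= DT); use eqd2_from_bnct() bin-wise")
  bed <- fractions * (x$dose - params$Dq) / (params$alpha * params$D0)
  e <- bed / (1 + 2 * params$beta / params$alpha)
  dvh(e, x$volume, kind = x$kind, unit = "Gy", target = x$target)
}
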