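#' Simulate clonogenic survival data
#'
#' Generates surviving fractions on a dose grid from a known survival model
#' with multiplicative lognormal noise: `S_i = exp(lnS(d_i) + eps_i)` with
#' `eps_i ~ N(0, sigma^2)`, clipped into (0, 1]. Noise is normal on the lnS
#' scale, matching the least-squares objective of [fit_survival_model()].
#' The default grid (0.5 to 12 Gy in 0.5 Gy steps, 24 points) spans both
#' branches of the default USC parameters (transition at 4.66 Gy), the dose
#' range typical of clonogenic assays.
#'
#' @param true_params A `survival_params` object (default [usc_params_scc()]).
#' @param dose_grid Doses in Gy (default `seq(0.5, 12, by = 0.5)`).
#' @param noise_sigma Lognormal sigma of S, i.e. SD of the lnS noise
#'   (default 0.1, a realistic clonogenic-assay scatter).
#' @param replicates Number of independent datasets (default 1).
#' @param seed Integer seed; same seed, same data.
#' @return A survival data frame (`dose_Gy`, `survival_fraction`), or a list
#'   of them when `replicates > 1`.
#' @examples
#' dat <- simulate_survival_data(seed = 7)
#' fit_survival_model(dat, "usc")$see
#' @export
simulate_survival_data <- function(true_params = usc_params_scc(),
                                   dose_grid = seq(0.5, 12, by = 0.5),
                                   noise_sigma = 0.1, replicates = 1L,
                                   seed = NULL) {
  stopifnot(inherits(true_params, "survival_params"))
  stop_if(noise_sigma < 0, "'noise_sigma' must be >= 0")
  dose_grid <- sort(unique(check_dose_vec(dose_grid)))
  if (!is.null(seed)) set.seed(seed)
  one <- function() {
    lnS <- ln_survival(true_params, dose_grid)
    eps <- if (noise_sigma > 0) stats::rnorm(length(dose_grid), 0, noise_sigma) else 0
    s <- pmin(exp(lnS + eps), 1)
    s <- pmax(s, .Machine$double.xmin)
    data.frame(dose_Gy = dose_grid, survival_fraction = s)
  }
  if (replicates == 1L) one() else replicate(replicates, one(), simplify = FALSE)
}

#' Simulate a parametric tumor DVH
#'
#' Builds a differential weighted-dose DVH with two knobs that reproduce the
#' clinically decisive cold-spot phenomenology: the exact minimum dose and
#' the volume fraction below a cold-spot edge. The histogram is the sum of
#'
#' * a *cold tail* on `[min_dose, cold_edge)` holding exactly
#'   `cold_spot_volume` of the structure. Its cumulative volume grows as the
#'   cube of the dose distance from the minimum — the volume of an
#'   approximately point-like underdosed region grows like the cube of its
#'   linear extent — so only a sliver of volume sits at the very minimum. The
#'   bin at exactly `min_dose` receives an atom of
#'   `cold_min_split * cold_spot_volume` (default split 1e-3, a single-voxel
#'   scale for a tumor resolved into thousands of voxels);
#' * a *main mass* of `1 - cold_spot_volume` on `[cold_edge, max_dose]`,
#'   shaped as a discretized scaled Beta density with mode `modal_dose`
#'   (`shape = "beta-like"`) or a two-component Beta mixture
#'   (`shape = "bimodal"`), optionally jittered bin-wise by lognormal factors
#'   when a seed is given.
#'
#' By construction `volume_fraction_below(result, cold_edge)` equals
#' `cold_spot_volume` exactly and `min_dose(result)` equals `min_dose`.
#'
#' @param min_dose Exact minimum dose of the structure (Gy-w).
#' @param modal_dose Mode of the main dose mass (Gy-w).
#' @param max_dose Maximum dose (Gy-w).
#' @param cold_spot_volume Volume fraction below `cold_edge`, in `[0, 0.5]`.
#' @param cold_edge Upper edge of the cold region (default 18.5 Gy-w, the
#'   threshold used when contrasting under-dosed targets).
#' @param cold_min_split Fraction of the cold volume placed as an atom at
#'   exactly `min_dose` (default 0.001).
#' @param bin_width Histogram resolution (default 0.1 Gy-w).
#' @param shape `"beta-like"` or `"bimodal"`.
#' @param jitter_sd Lognormal sigma of the per-bin jitter on the main mass
#'   (default 0.05; applied only when `seed` is given).
#' @param seed Integer seed for the jitter; `NULL` gives the deterministic
#'   unjittered shape.
#' @param target Structure label.
#' @return A differential [dvh] in Gy-w.
#' @examples
#' h <- simulate_dvh(9.3, modal_dose = 24, max_dose = 30,
#'                   cold_spot_volume = 0.15)
#' volume_fraction_below(h, 18.5)   # exactly 0.15
#' @export
simulate_dvh <- function(min_dose, modal_dose, max_dose,
                         cold_spot_volume = 0, cold_edge = 18.5,
                         cold_min_split = 0.001, bin_width = 0.1,
                         shape = c("beta-like", "bimodal"),
                         jitter_sd = 0.05, seed = NULL, target = "") {
  shape <- match.arg(shape)
  min_dose <- check_num(min_dose, "min_dose", 0, strict = TRUE)
  modal_dose <- check_num(modal_dose, "modal_dose", 0, strict = TRUE)
  max_dose <- check_num(max_dose, "max_dose", 0, strict = TRUE)
  cold <- check_num(cold_spot_volume, "cold_spot_volume", 0)
  stop_if(cold > 0.5, "'cold_spot_volume' must be in [0, 0.5]")
  stop_if(modal_dose > max_dose, "'modal_dose' must be <= max_dose")
  if (min_dose == max_dose) {
    stop_if(cold > 0, "degenerate uniform DVH cannot carry a cold spot")
    return(dvh(min_dose, 1, target = target))
  }
  stop_if(min_dose >= modal_dose, "'min_dose' must be < modal_dose")
  if (cold > 0) {
    stop_if(cold_edge <= min_dose || cold_edge >= max_dose,
            "'cold_edge' must lie strictly between min_dose and max_dose")
  }
  if (!is.null(seed)) set.seed(seed)

  w <- bin_width
  doses <- numeric(0)
  vols <- numeric(0)
  if (cold > 0) {
    edges <- seq(min_dose, cold_edge, by = w)
    if (edges[[length(edges)]] < cold_edge) edges <- c(edges, cold_edge)
    cdf <- ((edges - min_dose) / (cold_edge - min_dose))^3
    doses <- edges[-length(edges)]                       # left edges, all < cold_edge
    vols <- diff(cdf) * cold * (1 - cold_min_split)
    vols[[1L]] <- vols[[1L]] + cold * cold_min_split     # exact-minimum atom
  }
  lo <- if (cold > 0) cold_edge else min_dose
  main_mass <- 1 - cold
  if (max_dose - lo < w) {
    doses <- c(doses, max_dose)
    vols <- c(vols, main_mass)
  } else {
    edges <- seq(lo, max_dose, by = w)
    if (edges[[length(edges)]] < max_dose) edges <- c(edges, max_dose)
    t_mode <- min(max((modal_dose - lo) / (max_dose - lo), 0.02), 0.98)
    kappa <- 8
    pb <- function(m) {
      stats::pbeta((edges - lo) / (max_dose - lo),
                   1 + m * (kappa - 2), 1 + (1 - m) * (kappa - 2))
    }
    cdf <- if (shape == "beta-like") {
      pb(t_mode)
    } else {
      m2 <- if (t_mode <= 0.55) min(t_mode + 0.35, 0.98) else max(t_mode - 0.35, 0.02)
      0.6 * pb(t_mode) + 0.4 * pb(m2)
    }
    mv <- diff(cdf)
    if (!is.null(seed) && jitter_sd > 0) {
      mv <- mv * exp(stats::rnorm(length(mv), 0, jitter_sd))
    }
    mv <- mv / sum(mv) * main_mass
    doses <- c(doses, edges[-length(edges)])
    vols <- c(vols, mv)
  }
  keep <- vols > 0 | seq_along(vols) == 1L    # keep the exact-minimum bin
  dvh(doses[keep], vols[keep], target = target)
}

#' Simulate a synthetic patient cohort
#'
#' Draws `n` single-target patients with varied minimum doses, dose spreads
#' and cold-spot volumes so that the resulting TCPs span the full 0-100%
#' range and all three response classes. Deterministic per seed.
#'
#' @param n Number of patients, `>= 1`.
#' @param seed Integer seed.
#' @param shape Passed to [simulate_dvh()].
#' @return List of [patient_record()] objects.
#' @examples
#' cohort <- simulate_cohort(4, seed = 1)
#' run_cohort(cohort)
#' @export
simulate_cohort <- function(n, seed = 1L, shape = "beta-like") {
  stop_if(!is.numeric(n) || n < 1 || n != round(n), "'n' must be a positive integer")
  set.seed(seed)
  mins <- stats::runif(n, 6, 25)
  spreads <- stats::runif(n, 5, 14)
  mode_pos <- stats::runif(n, 0.55, 0.9)
  colds <- ifelse(mins < 18.5, stats::runif(n, 0.02, 0.25), 0)
  sub_seeds <- sample.int(1e6, n)
  lapply(seq_len(n), function(i) {
    maxd <- mins[[i]] + spreads[[i]]
    edge <- min(18.5, mins[[i]] + 0.6 * spreads[[i]])
    modal <- max(mins[[i]] + mode_pos[[i]] * spreads[[i]], edge + 0.1)
    modal <- min(modal, maxd)
    h <- simulate_dvh(mins[[i]], modal, maxd,
                      cold_spot_volume = colds[[i]], cold_edge = edge,
                      shape = shape, seed = sub_seeds[[i]],
                      target = "GTV1")
    patient_record(sprintf("sim%02d", i), list(GTV1 = h))
  })
}
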