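# Shared fixtures for the test suite.

# Published SCC coefficients (USC model)
scc <- list(alpha = 0.2111, beta = 0.0890, D0 = 0.9603, Dq = 1.8588,
            DT = 4.6628)

scc_params <- function() usc_params_scc()

# Published per-target cohort summary (gEUD -> TCP fixture)
read_cohort_summary <- function() {
  path <- system.file("extdata", "hn_cohort_summary.csv", package = "bnctcp")
  utils::read.csv(path, comment.char = "#", strip.white = TRUE)
}

# Brute-force gEUD oracle: naive power sum, no log-space tricks
geud_naive <- function(dose, volume, a) {
  (sum(volume * dose^a))^(1 / a)
}

# Random valid differential DVH with doses in [lo, hi]
random_dvh <- function(n_bins = NULL, lo = 5, hi = 100) {
  if (is.null(n_bins)) n_bins <- sample(2:40, 1L)
  dose <- sort(runif(n_bins, lo, hi))
  while (anyDuplicated(dose)) dose <- sort(runif(n_bins, lo, hi))
  v <- rgamma(n_bins, 1)
  dvh(dose, v / sum(v), unit = "Gy")
}
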