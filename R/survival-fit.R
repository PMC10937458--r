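#' Read and validate a clonogenic survival dataset
#'
#' Reads delimited text (comma or tab, auto-detected) with header columns
#' `dose_Gy` and `survival_fraction`, one observation per row; lines starting
#' with `#` are ignored. Rows are sorted by dose. Surviving fractions must lie
#' in (0, 1]; doses must be non-negative and unique.
#'
#' @param path Path to the text file.
#' @return A data frame with columns `dose_Gy`, `survival_fraction` and, if
#'   present in the file, `weight`.
#' @export
read_survival_data <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  stop_if(length(lines) < 2L, "survival data file has no data rows: ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          strip.white = TRUE)
  stop_if(!all(c("dose_Gy", "survival_fraction") %in% names(df)),
          "expected header 'dose_Gy,survival_fraction' in ", path)
  validate_survival_data(df)
}

validate_survival_data <- function(df) {
  stop_if(!is.data.frame(df) || nrow(df) == 0L,
          "survival data must be a non-empty data frame")
  d <- df$dose_Gy
  s <- df$survival_fraction
  stop_if(any(!is.finite(d)) || any(d < 0), "doses must be finite and >= 0")
  stop_if(any(!is.finite(s)) || any(s <= 0) || any(s > 1),
          "surviving fractions must lie in (0, 1]")
  df <- df[order(d), , drop = FALSE]
  stop_if(anyDuplicated(df$dose_Gy) > 0L, "doses must be unique")
  rownames(df) <- NULL
  df
}

#' @rdname read_survival_data
#' @param data Survival data frame as returned by [read_survival_data()].
#' @param path Destination path.
#' @export
write_survival_data <- function(data, path) {
  data <- validate_survival_data(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Model-specific bridge between the optimizer's free-parameter vector and a
# typed parameter object. USC is reparameterized as (alpha, x = alpha*D0, Dq)
# so the box constraint x < 1 keeps the multi-target branch valid; beta and DT
# follow from the smooth-join relations and are never free.
fit_spec <- function(kind) {
  switch(kind,
    lq = list(
      names = c("alpha", "beta"),
      lower = c(1e-8, 1e-10), upper = c(3, 2),
      to_params = function(th) survival_params_lq(th[1L], th[2L])),
    usc = list(
      names = c("alpha", "x", "Dq"),
      lower = c(1e-4, 0.01, 1e-3), upper = c(3, 0.99, 20),
      to_params = function(th) {
        alpha <- th[1L]; x <- th[2L]; Dq <- th[3L]
        survival_params_usc(alpha = alpha, D0 = x / alpha, Dq = Dq)
      }),
    lql = list(
      names = c("alpha", "beta", "DT"),
      lower = c(1e-8, 1e-10, 0.1), upper = c(3, 2, 30),
      to_params = function(th) survival_params_lql(th[1L], th[2L], th[3L])),
    plq = list(
      names = c("alpha", "beta", "gamma"),
      lower = c(1e-8, 1e-10, 0), upper = c(3, 2, 5),
      to_params = function(th) survival_params_plq(th[1L], th[2L], th[3L])),
    stop("unknown model kind: ", kind))
}

# Seeded Latin-hypercube starts within the box [lower, upper].
lhs_starts <- function(n, lower, upper, seed) {
  k <- length(lower)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  u <- vapply(seq_len(k), function(j) (sample(n) - stats::runif(n)) / n,
              numeric(n))
  u <- matrix(u, nrow = n)
  sweep(sweep(u, 2L, upper - lower, `*`), 2L, lower, `+`)
}

# Data-driven start: LQ regression on the low-dose half for (alpha, beta),
# straight-line tail for (1/D0, Dq/D0).
heuristic_start <- function(kind, d, y) {
  n <- length(d)
  lo <- seq_len(max(3L, floor(n / 2)))
  X <- cbind(d[lo], d[lo]^2)
  ab <- tryCatch(-stats::lsfit(X, y[lo], intercept = FALSE)$coefficients,
                 error = function(e) c(0.2, 0.05))
  ab <- pmax(ab, c(1e-4, 1e-6))
  hi <- seq.int(max(1L, n - max(3L, floor(n / 3)) + 1L), n)
  tail_fit <- tryCatch(stats::lsfit(d[hi], y[hi])$coefficients,
                       error = function(e) c(1, -1))
  slope <- min(tail_fit[[2L]], -1e-3)
  D0 <- -1 / slope
  Dq <- max(tail_fit[[1L]] * D0, 0.05)
  spec <- fit_spec(kind)
  th <- switch(kind,
    lq = ab,
    usc = c(ab[[1L]], min(max(ab[[1L]] * D0, 0.02), 0.95), Dq),
    lql = c(ab[[1L]], ab[[2L]], max(2 * Dq, 1)),
    plq = c(ab[[1L]], ab[[2L]], 0.05))
  pmin(pmax(th, spec$lower), spec$upper)
}

#' Fit a cell-survival model to clonogenic data
#'
#' Least-squares fit in ln-survival space. For the USC model the free
#' parameters are (alpha, D0, Dq); beta and the transition dose are tied to
#' them by the smooth-join constraints
#' `beta = (1 - alpha*D0)^2 / (4*Dq*D0)` and `DT = 2*Dq / (1 - alpha*D0)`,
#' so the fitted curve is always C1 at the join. The objective is minimized by
#' bounded quasi-Newton iterations from a data-driven start plus `n_restarts`
#' seeded Latin-hypercube starts (the piecewise objective has local minima).
#'
#' @param data Data frame with columns `dose_Gy`, `survival_fraction`, and
#'   optionally `weight` (see [read_survival_data()]).
#' @param model One of `"lq"`, `"usc"`, `"lql"`, `"plq"`.
#' @param weights Optional per-point weights; defaults to the `weight` column
#'   if present, else unweighted.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Seed for the restart design (default 20240229).
#' @return An object of class `survival_fit`: list with `model`, `params`
#'   (typed parameter object), `see` (residual standard error in lnS space,
#'   denominator N - p), `residuals`, `n_points`, `n_free_params`, `sse`,
#'   `converged`.
#' @examples
#' dat <- simulate_survival_data(noise_sigma = 0, seed = 1)
#' fit <- fit_survival_model(dat, "usc")
#' fit$params$alpha
#' @export
fit_survival_model <- function(data, model = c("lq", "usc", "lql", "plq"),
                               weights = NULL, n_restarts = 10L,
                               seed = 20240229L) {
  model <- match.arg(model)
  data <- validate_survival_data(data)
  spec <- fit_spec(model)
  p <- n_free_params(model)
  n <- nrow(data)
  stop_if(n < p + 2L,
          sprintf("need at least %d points to fit the %s model, got %d",
                  p + 2L, toupper(model), n))
  d <- data$dose_Gy
  y <- log(data$survival_fraction)
  w <- if (!is.null(weights)) weights else if (!is.null(data$weight)) data$weight else rep(1, n)
  stop_if(length(w) != n || any(!is.finite(w)) || any(w < 0),
          "weights must be non-negative, finite, one per point")

  obj <- function(th) {
    pr <- tryCatch(spec$to_params(th), error = function(e) NULL)
    if (is.null(pr)) return(1e12)
    r <- y - ln_survival(pr, d)
    sum(w * r^2)
  }
  starts <- rbind(heuristic_start(model, d, y),
                  lhs_starts(n_restarts, spec$lower, spec$upper, seed))
  ctrl <- list(maxit = 1000L, factr = 1e3,
               ndeps = rep(1e-7, length(spec$lower)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = spec$lower, upper = spec$upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  stop_if(is.null(best),
          sprintf("%s fit failed to converge from any start", toupper(model)))
  # simplex polish: the piecewise objective's finite-difference gradients can
  # stall L-BFGS-B short of the optimum
  pol <- tryCatch(
    stats::optim(best$par, function(th) {
      if (any(th < spec$lower) || any(th > spec$upper)) return(1e12)
      obj(th)
    }, method = "Nelder-Mead",
    control = list(maxit = 2000L, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) best <- pol
  pol2 <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B",
                 lower = spec$lower, upper = spec$upper, control = ctrl),
    error = function(e) NULL)
  if (!is.null(pol2) && pol2$value < best$value) best <- pol2
  params <- spec$to_params(best$par)
  resid <- y - ln_survival(params, d)
  sse <- sum(w * resid^2)
  structure(list(model = model, params = params,
                 see = sqrt(sse / (n - p)),
                 residuals = resid, n_points = n, n_free_params = p,
                 sse = sse, converged = best$convergence == 0L),
            class = "survival_fit")
}

#' Standard error of the estimate in ln-survival space
#'
#' `sqrt(sum((lnS_obs - lnS_pred)^2) / (N - p))` where `p` is the number of
#' free parameters of the model kind (2 for LQ, 3 for USC/LQL/PLQ). This is
#' the statistic used to rank candidate survival models.
#'
#' @inheritParams fit_survival_model
#' @param params A typed `survival_params` object consistent with `model`.
#' @return Non-negative scalar.
#' @export
standard_error_of_estimate <- function(data, model, params, weights = NULL) {
  data <- validate_survival_data(data)
  p <- n_free_params(model)
  n <- nrow(data)
  stop_if(n <= p, sprintf("SEE undefined: N = %d <= p = %d", n, p))
  y <- log(data$survival_fraction)
  w <- if (!is.null(weights)) weights else rep(1, n)
  r <- y - ln_survival(params, data$dose_Gy)
  sqrt(sum(w * r^2) / (n - p))
}

#' Rank survival models by goodness of fit
#'
#' Fits all four models to the same dataset and ranks them by ascending
#' standard error of the estimate; ties (within `tie_tol`) are broken in
#' favour of the model with fewer free parameters. A model whose fit fails is
#' recorded with `SEE = Inf` and ranked last.
#'
#' @inheritParams fit_survival_model
#' @param tie_tol Absolute SEE difference treated as a tie (default 1e-8).
#' @return A data frame with one row per model (`model`, `see`,
#'   `n_free_params`, `converged`) in rank order; the fitted objects are
#'   attached as attribute `"fits"`.
#' @examples
#' dat <- simulate_survival_data(noise_sigma = 0.1, seed = 42)
#' compare_models(dat)
#' @export
compare_models <- function(data, weights = NULL, n_restarts = 10L,
                           seed = 20240229L, tie_tol = 1e-8) {
  kinds <- c("lq", "usc", "lql", "plq")
  fits <- lapply(kinds, function(k) {
    tryCatch(fit_survival_model(data, k, weights = weights,
                                n_restarts = n_restarts, seed = seed),
             error = function(e) structure(list(model = k, error = conditionMessage(e)),
                                           class = "survival_fit_failure"))
  })
  names(fits) <- kinds
  tab <- data.frame(
    model = kinds,
    see = vapply(fits, function(f) if (inherits(f, "survival_fit")) f$see else Inf, 0),
    n_free_params = vapply(kinds, n_free_params, 0L),
    converged = vapply(fits, function(f) isTRUE(f$converged), FALSE),
    stringsAsFactors = FALSE)
  # tie-aware ordering: quantize SEE to tie_tol, then fewer free params first
  key <- round(tab$see / tie_tol)
  tab <- tab[order(key, tab$n_free_params), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<%s fit: %d points, %d free parameters>\n",
              toupper(x$model), x$n_points, x$n_free_params))
  cat(sprintf("  SEE (lnS space): %.6g%s\n", x$see,
              if (x$converged) "" else "  [not converged]"))
  print(x$params)
  invisible(x)
}
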