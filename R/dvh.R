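#' Dose-volume histograms
#'
#' A `dvh` object holds a binned dose-volume histogram for one target
#' structure: a strictly increasing dose grid with either differential
#' fractional volumes (point mass per bin, summing to 1) or cumulative
#' fractional volumes (fraction of the structure receiving at least each
#' dose, non-increasing from 1).
#'
#' Differential volumes whose sum differs from 1 by at most 1% are
#' renormalized with a message; a larger discrepancy is an error. Cumulative
#' histograms must start within 1% of 1 and are rescaled likewise.
#'
#' @param dose Strictly increasing numeric vector of bin doses.
#' @param volume Fractional volumes, same length as `dose`.
#' @param kind `"differential"` or `"cumulative"`.
#' @param unit Dose unit label, typically `"Gy-w"` (weighted BNCT dose) or
#'   `"Gy"` (EQD2).
#' @param target Free-text structure label (e.g. `"GTV1"`).
#' @return An object of class `dvh`.
#' @examples
#' h <- dvh(c(10, 20, 30), c(0.2, 0.5, 0.3))
#' mean_dose(h)
#' to_cumulative(h)$volume
#' @export
dvh <- function(dose, volume, kind = c("differential", "cumulative"),
                unit = "Gy-w", target = "") {
  kind <- match.arg(kind)
  stop_if(length(dose) == 0L, "empty DVH")
  stop_if(length(dose) != length(volume), "dose and volume lengths differ")
  stop_if(any(!is.finite(dose)) || any(!is.finite(volume)),
          "dose and volume must be finite")
  stop_if(any(dose < 0), "doses must be >= 0")
  stop_if(is.unsorted(dose, strictly = TRUE), "doses must be strictly increasing")
  stop_if(any(volume < 0), "volumes must be >= 0")
  if (kind == "differential") {
    s <- sum(volume)
    stop_if(abs(s - 1) > 0.01,
            sprintf("differential volumes sum to %.4f, outside [0.99, 1.01]", s))
    if (s != 1) {
      if (abs(s - 1) > 1e-6) {
        message(sprintf("renormalizing differential volumes (sum %.4f -> 1)", s))
      }
      volume <- volume / s
    }
  } else {
    stop_if(is.unsorted(rev(volume)), "cumulative volumes must be non-increasing")
    stop_if(abs(volume[[1L]] - 1) > 0.01,
            sprintf("cumulative volume at the lowest dose is %.4f, outside [0.99, 1.01]",
                    volume[[1L]]))
    if (volume[[1L]] != 1) {
      if (abs(volume[[1L]] - 1) > 1e-6) {
        message(sprintf("rescaling cumulative volumes (start %.4f -> 1)", volume[[1L]]))
      }
      volume <- volume / volume[[1L]]
    }
  }
  structure(list(dose = as.numeric(dose), volume = as.numeric(volume),
                 kind = kind, unit = unit, target = as.character(target)),
            class = "dvh")
}

#' Read / write the package's DVH text format
#'
#' The format is a single header line
#' `# kind=<differential|cumulative> unit=<unit> target=<label>` followed by
#' `dose,volume` CSV rows. Additional `#` lines are ignored.
#' `write_dvh()` followed by `read_dvh()` is the identity up to text float
#' precision.
#'
#' @param path Path of the DVH text file.
#' @return `read_dvh()` returns a [dvh] object; `write_dvh()` returns `path`
#'   invisibly.
#' @export
read_dvh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_i <- grep("^#\\s*kind=", lines)
  stop_if(length(hdr_i) != 1L,
          "expected exactly one '# kind=... unit=... target=...' header line in ", path)
  hdr <- lines[[hdr_i]]
  field <- function(key, default = NULL) {
    m <- regmatches(hdr, regexec(paste0(key, "=(\\S*)"), hdr))[[1L]]
    if (length(m) < 2L) {
      stop_if(is.null(default), "missing '", key, "=' in DVH header: ", hdr)
      return(default)
    }
    m[[2L]]
  }
  kind <- field("kind")
  stop_if(!kind %in% c("differential", "cumulative"),
          "DVH kind must be 'differential' or 'cumulative', got '", kind, "'")
  unit <- field("unit", "Gy-w")
  target <- field("target", "")
  body <- lines[-seq_len(hdr_i)]
  body <- body[!grepl("^\\s*#", body) & nzchar(trimws(body))]
  stop_if(length(body) == 0L, "no DVH rows in ", path)
  if (grepl("dose", body[[1L]], ignore.case = TRUE)) body <- body[-1L]
  df <- tryCatch(
    utils::read.table(text = body, sep = ",", col.names = c("dose", "volume")),
    error = function(e) stop("malformed DVH rows in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  tryCatch(dvh(df$dose, df$volume, kind = kind, unit = unit, target = target),
           error = function(e) stop("invalid DVH in ", path, " (data starting line ",
                                    hdr_i + 1L, "): ", conditionMessage(e),
                                    call. = FALSE))
}

#' @rdname read_dvh
#' @param x A [dvh] object.
#' @export
write_dvh <- function(x, path) {
  stopifnot(inherits(x, "dvh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s unit=%s target=%s", x$kind, x$unit, x$target), con)
  writeLines("dose,volume", con)
  writeLines(sprintf("%.10g,%.10g", x$dose, x$volume), con)
  invisible(path)
}

#' Convert between differential and cumulative DVHs
#'
#' Cumulative-to-differential converts by successive differencing (the volume
#' beyond the last bin is taken as zero); differential-to-cumulative by suffix
#' summation. The round trip is the identity to floating-point precision. An
#' object already in the requested kind is returned unchanged (copy).
#'
#' @param x A [dvh] object.
#' @return A [dvh] of the requested kind.
#' @export
to_differential <- function(x) {
  stopifnot(inherits(x, "dvh"))
  if (x$kind == "differential") return(x)
  v <- c(-diff(x$volume), x$volume[[length(x$volume)]])
  dvh(x$dose, v, kind = "differential", unit = x$unit, target = x$target)
}

#' @rdname to_differential
#' @export
to_cumulative <- function(x) {
  stopifnot(inherits(x, "dvh"))
  if (x$kind == "cumulative") return(x)
  v <- rev(cumsum(rev(x$volume)))
  dvh(x$dose, v, kind = "cumulative", unit = x$unit, target = x$target)
}

#' Dose metrics of a DVH
#'
#' `min_dose()`/`max_dose()` are the lowest/highest dose carrying nonzero
#' differential volume; `mean_dose()` is the volume-weighted mean
#' \eqn{\sum_i v_i D_i}. `volume_fraction_below()` is the differential volume
#' strictly below `threshold`. `dose_at_volume()` is the largest dose at
#' which the cumulative volume still reaches `volume_fraction`, with linear
#' interpolation between cumulative points (a D80-style coverage metric).
#'
#' @param x A [dvh] object (either kind; converted internally).
#' @param threshold Dose threshold (same unit as `x`).
#' @param volume_fraction Fraction in (0, 1].
#' @return A scalar dose or volume fraction.
#' @examples
#' h <- dvh(c(10, 20, 30), c(1, 0.8, 0.3), kind = "cumulative")
#' dose_at_volume(h, 0.55)   # 25 by interpolation
#' volume_fraction_below(h, 18.5)
#' @export
min_dose <- function(x) {
  d <- to_differential(x)
  nz <- d$volume > 1e-12
  stop_if(!any(nz), "DVH has no nonzero-volume bin")
  min(d$dose[nz])
}

#' @rdname min_dose
#' @export
max_dose <- function(x) {
  d <- to_differential(x)
  nz <- d$volume > 1e-12
  stop_if(!any(nz), "DVH has no nonzero-volume bin")
  max(d$dose[nz])
}

#' @rdname min_dose
#' @export
mean_dose <- function(x) {
  d <- to_differential(x)
  sum(d$volume * d$dose)
}

#' @rdname min_dose
#' @export
volume_fraction_below <- function(x, threshold) {
  d <- to_differential(x)
  sum(d$volume[d$dose < threshold])
}

#' @rdname min_dose
#' @export
dose_at_volume <- function(x, volume_fraction) {
  stop_if(!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
            volume_fraction <= 0 || volume_fraction > 1,
          "'volume_fraction' must be a single value in (0, 1]")
  cum <- to_cumulative(x)
  d <- cum$dose
  v <- cum$volume
  if (volume_fraction <= v[[length(v)]]) return(d[[length(d)]])
  if (volume_fraction >= v[[1L]]) return(d[[1L]])
  # v is non-increasing; find the segment [i, i+1] bracketing the fraction
  i <- max(which(v >= volume_fraction))
  if (v[[i]] == volume_fraction) return(d[[i]])
  frac <- (v[[i]] - volume_fraction) / (v[[i]] - v[[i + 1L]])
  d[[i]] + frac * (d[[i + 1L]] - d[[i]])
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<%s DVH%s: %d bins, unit %s>\n", x$kind,
              if (nzchar(x$target)) paste0(" [", x$target, "]") else "",
              length(x$dose), x$unit))
  cat(sprintf("  dose range %.4g - %.4g, mean %.4g\n",
              min_dose(x), max_dose(x), mean_dose(x)))
  invisible(x)
}

#' @export
format.dvh <- function(x, ...) {
  sprintf("%s DVH (%d bins, %s)", x$kind, length(x$dose), x$unit)
}
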