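#' Patient record for TCP evaluation
#'
#' Bundles one patient's target DVHs (weighted dose, Gy-w) with an optional
#' observed RECIST response. A patient can have several targets (e.g. GTV1,
#' GTV2); labels must be unique.
#'
#' @param patient_id Identifier string.
#' @param targets Named list of [dvh] objects; names are target labels. An
#'   unnamed single DVH is labelled `"GTV1"`.
#' @param observed_response Optional `"CR"`, `"PR"`, `"SD"` or `"PD"`.
#' @return A classed list `patient_record`.
#' @export
patient_record <- function(patient_id, targets, observed_response = NA_character_) {
  if (inherits(targets, "dvh")) targets <- list(GTV1 = targets)
  stop_if(!is.list(targets) || length(targets) == 0L,
          "'targets' must be a non-empty list of dvh objects")
  stop_if(!all(vapply(targets, inherits, TRUE, "dvh")),
          "every target must be a dvh object")
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    names(targets) <- paste0("GTV", seq_along(targets))
  }
  stop_if(anyDuplicated(names(targets)) > 0L, "target labels must be unique")
  if (!is.na(observed_response)) {
    stop_if(!observed_response %in% c("CR", "PR", "SD", "PD"),
            "'observed_response' must be one of CR, PR, SD, PD")
  }
  structure(list(patient_id = as.character(patient_id), targets = targets,
                 observed_response = observed_response),
            class = "patient_record")
}

#' Weighted-dose DVH to TCP, end to end
#'
#' The two-step evaluation used throughout the package: (1) convert each
#' target's weighted-dose DVH to EQD2 via the USC single-delivery isoeffect
#' relation; (2) reduce the EQD2 distribution to its gEUD and evaluate the
#' logistic TCP, then classify the TCP against the CR/PR response levels.
#'
#' @param record A [patient_record()].
#' @param usc A `survival_params_usc` object (default [usc_params_scc()]).
#' @param tcp A [tcp_params()] object.
#' @param fractions Fractions for the EQD2 conversion (default 1, the
#'   single-delivery reading under which published per-target doses are
#'   reproduced).
#' @return A data frame with one row per target: `patient_id`, `target`,
#'   `dbnct_min_gyw` (minimum weighted dose), `geud_gy`, `tcp_percent`
#'   (full precision; see [format_tcp_report()] for 1-decimal reporting),
#'   `response_class`, `observed_response`. The per-target EQD2 DVHs are
#'   attached as attribute `"eqd2"`.
#' @examples
#' h <- dvh(20, 1)   # uniform 20 Gy-w
#' run_patient(patient_record("demo", h))
#' @export
run_patient <- function(record, usc = usc_params_scc(), tcp = tcp_params(),
                        fractions = 1L) {
  stopifnot(inherits(record, "patient_record"))
  labels <- names(record$targets)
  eqd2_list <- vector("list", length(labels))
  names(eqd2_list) <- labels
  rows <- lapply(seq_along(labels), function(i) {
    lab <- labels[[i]]
    h <- record$targets[[i]]
    res <- tryCatch({
      e <- suppressWarnings(eqd2_dvh(h, params = usc, fractions = fractions))
      g <- geud(e, a = tcp$a)
      t_ <- tcp_from_geud(g, tcp)
      eqd2_list[[i]] <<- e
      data.frame(patient_id = record$patient_id, target = lab,
                 dbnct_min_gyw = min_dose(h), geud_gy = g, tcp_percent = t_,
                 response_class = as.character(classify_response(t_)),
                 observed_response = record$observed_response,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      stop(sprintf("patient %s, target %s: %s", record$patient_id, lab,
                   conditionMessage(e)), call. = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "eqd2") <- eqd2_list
  out
}

#' Evaluate a cohort of patients
#'
#' Runs [run_patient()] over a list of records. Per-patient failures are
#' collected rather than aborting the run; the summary counts targets per
#' response class.
#'
#' @inheritParams run_patient
#' @param records Non-empty list of [patient_record()] objects.
#' @return A list of class `tcp_cohort`: `results` (row-bound report, one row
#'   per patient-target), `summary` (named counts per response class),
#'   `failures` (named character vector of error messages, possibly empty).
#' @export
run_cohort <- function(records, usc = usc_params_scc(), tcp = tcp_params(),
                       fractions = 1L) {
  stop_if(!is.list(records) || length(records) == 0L,
          "'records' must be a non-empty list of patient_record objects")
  stop_if(!all(vapply(records, inherits, TRUE, "patient_record")),
          "every element must be a patient_record")
  results <- list()
  failures <- character()
  for (rec in records) {
    out <- tryCatch(run_patient(rec, usc = usc, tcp = tcp, fractions = fractions),
                    error = function(e) conditionMessage(e))
    if (is.character(out)) {
      failures[[rec$patient_id]] <- out
    } else {
      attr(out, "eqd2") <- NULL
      results[[length(results) + 1L]] <- out
    }
  }
  res <- if (length(results)) do.call(rbind, results) else NULL
  counts <- if (is.null(res)) integer(0) else table(factor(
    res$response_class, levels = c("sub-PR", "PR-level", "CR-level")))
  structure(list(results = res, summary = counts, failures = failures),
            class = "tcp_cohort")
}

round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a TCP report for presentation
#'
#' Rounds dose and TCP columns to one decimal (half-up) for display or CSV
#' export. Rounding happens only here; upstream values are full precision.
#'
#' @param report Data frame from [run_patient()] or `run_cohort()$results`.
#' @return Data frame with rounded numeric columns.
#' @export
format_tcp_report <- function(report) {
  stopifnot(is.data.frame(report))
  for (col in intersect(c("dbnct_min_gyw", "geud_gy", "tcp_percent"),
                        names(report))) {
    report[[col]] <- round_half_up(report[[col]], 1L)
  }
  report
}

#' @export
print.tcp_cohort <- function(x, ...) {
  n_pat <- if (is.null(x$results)) 0L else length(unique(x$results$patient_id))
  cat(sprintf("<TCP cohort report: %d patients, %d targets, %d failures>\n",
              n_pat, if (is.null(x$results)) 0L else nrow(x$results),
              length(x$failures)))
  if (!is.null(x$results)) {
    print(format_tcp_report(x$results), row.names = FALSE)
    cat("response classes: ",
        paste(sprintf("%s=%d", names(x$summary), x$summary), collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$failures)) {
    cat("failures:\n")
    for (id in names(x$failures)) cat("  ", id, ": ", x$failures[[id]], "\n", sep = "")
  }
  invisible(x)
}

#' Read a cohort manifest
#'
#' CSV with header `patient_id,target_label,dvh_path,response`; DVH paths are
#' resolved relative to the manifest's directory. Rows sharing a patient id
#' become one multi-target record.
#'
#' @param path Manifest CSV path.
#' @return List of [patient_record()] objects.
#' @export
read_cohort_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("patient_id", "target_label", "dvh_path")
  stop_if(!all(need %in% names(df)),
          "manifest must have columns patient_id,target_label,dvh_path[,response]")
  if (is.null(df$response)) df$response <- NA_character_
  base <- dirname(normalizePath(path))
  lapply(split(df, df$patient_id), function(g) {
    targets <- lapply(g$dvh_path, function(p) {
      if (!file.exists(p)) p <- file.path(base, p)
      read_dvh(p)
    })
    names(targets) <- g$target_label
    resp <- g$response[[1L]]
    if (is.null(resp) || is.na(resp) || !nzchar(resp)) resp <- NA_character_
    patient_record(g$patient_id[[1L]], targets, resp)
  })
}
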