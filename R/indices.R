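#' Albumin quotient (QAlb)
#'
#' The CSF-to-serum albumin concentration ratio, the standard proxy for
#' blood--CSF barrier permeability. Both concentrations must share the same
#' unit (the package convention is mg/L throughout).
#'
#' @param csf_albumin CSF albumin concentration (mg/L), strictly positive.
#' @param serum_albumin Serum albumin concentration (mg/L), strictly positive.
#' @return The dimensionless quotient `csf_albumin / serum_albumin`.
#'   Vectorized over its arguments.
#' @examples
#' albumin_quotient(200, 40000)  # 0.005
#' @export
albumin_quotient <- function(csf_albumin, serum_albumin) {
  check_positive(csf_albumin, "csf_albumin")
  check_positive(serum_albumin, "serum_albumin")
  csf_albumin / serum_albumin
}

#' IgM index (IgMi)
#'
#' The CSF-to-serum IgM quotient normalized by the albumin quotient:
#' \deqn{IgMi = \frac{Q_{IgM}}{Q_{Alb}} =
#'   \frac{IgM_{CSF}/IgM_{serum}}{Alb_{CSF}/Alb_{serum}}.}
#' Albumin normalization removes the contribution of passive transfer across
#' the blood--CSF barrier, so elevated values point to intrathecal synthesis.
#'
#' @param csf_igm,serum_igm CSF and serum IgM concentrations (mg/L).
#' @param csf_albumin,serum_albumin CSF and serum albumin concentrations (mg/L).
#' @return Dimensionless index; vectorized.
#' @examples
#' igm_index(1, 1000, 200, 40000)  # 0.2
#' @export
igm_index <- function(csf_igm, serum_igm, csf_albumin, serum_albumin) {
  check_positive(csf_igm, "csf_igm")
  check_positive(serum_igm, "serum_igm")
  (csf_igm / serum_igm) / albumin_quotient(csf_albumin, serum_albumin)
}

#' Free kappa light chain index (FKLCi)
#'
#' The CSF-to-serum free kappa light chain quotient normalized by the albumin
#' quotient, analogous to [igm_index()].
#'
#' @param csf_fklc,serum_fklc CSF and serum free kappa light chain
#'   concentrations (mg/L).
#' @param csf_albumin,serum_albumin CSF and serum albumin concentrations (mg/L).
#' @return Dimensionless index; vectorized.
#' @examples
#' fklc_index(1.25, 10, 200, 40000)  # 25
#' @export
fklc_index <- function(csf_fklc, serum_fklc, csf_albumin, serum_albumin) {
  check_positive(csf_fklc, "csf_fklc")
  check_positive(serum_fklc, "serum_fklc")
  (csf_fklc / serum_fklc) / albumin_quotient(csf_albumin, serum_albumin)
}

#' Compute the index panel for a cohort
#'
#' Derives `qalb`, `igmi` and `fklci` for every complete row of a cohort
#' table. Rows missing any of the six concentrations are dropped with a
#' message (complete-pair analysis; no imputation). Implausibly high albumin
#' quotients (QAlb > 0.05) trigger a warning but are retained: no exclusion
#' rule is applied to out-of-range values.
#'
#' @param cohort A data frame with columns `csf_igm`, `serum_igm`, `csf_fklc`,
#'   `serum_fklc`, `csf_albumin`, `serum_albumin`, and optionally
#'   `patient_id`, `ocmb_status` (0/1/NA), `activity`.
#' @return The input rows (complete cases only) with `qalb`, `igmi`, `fklci`
#'   columns appended.
#' @examples
#' compute_panel(data.frame(
#'   csf_igm = 1, serum_igm = 1000, csf_fklc = 1.25, serum_fklc = 10,
#'   csf_albumin = 200, serum_albumin = 40000
#' ))
#' @export
compute_panel <- function(cohort) {
  conc <- c("csf_igm", "serum_igm", "csf_fklc", "serum_fklc",
            "csf_albumin", "serum_albumin")
  missing_cols <- setdiff(conc, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(cohort[conc])
  if (any(!complete)) {
    dropped <- if ("patient_id" %in% names(cohort)) {
      paste(cohort$patient_id[!complete], collapse = ", ")
    } else {
      paste(which(!complete), collapse = ", ")
    }
    message("Dropping ", sum(!complete),
            " sample(s) with incomplete concentrations: ", dropped)
    cohort <- cohort[complete, , drop = FALSE]
  }
  if (nrow(cohort) == 0L) {
    stop("no complete samples left after removing missing concentrations",
         call. = FALSE)
  }
  cohort$qalb <- albumin_quotient(cohort$csf_albumin, cohort$serum_albumin)
  cohort$igmi <- igm_index(cohort$csf_igm, cohort$serum_igm,
                           cohort$csf_albumin, cohort$serum_albumin)
  cohort$fklci <- fklc_index(cohort$csf_fklc, cohort$serum_fklc,
                             cohort$csf_albumin, cohort$serum_albumin)
  if (any(cohort$qalb > 0.05)) {
    warning("QAlb > 0.05 for ", sum(cohort$qalb > 0.05),
            " sample(s); values retained (no plausibility exclusion)",
            call. = FALSE)
  }
  cohort
}

#' Read a cohort CSV
#'
#' Reads the package's cohort dialect: one row per patient, header required,
#' UTF-8, decimal point. Columns: `patient_id`, the six concentrations,
#' `ocmb_status` (0/1/NA) and optionally `activity`. Concentrations are
#' normalized to mg/L at this boundary: a `units` argument names the unit of
#' each analyte column ("mg/L", "g/L" or "mg/dL") and triggers conversion, so
#' mixed-unit sources cannot silently corrupt the (unit-free) indices.
#'
#' @param path Path to the CSV file.
#' @param units Optional named character vector mapping concentration column
#'   names to their unit, e.g. `c(serum_albumin = "g/L")`. Unlisted columns
#'   are assumed mg/L.
#' @return A data frame in canonical mg/L units.
#' @export
read_cohort <- function(path, units = NULL) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  required <- c("csf_igm", "serum_igm", "csf_fklc", "serum_fklc",
                "csf_albumin", "serum_albumin")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(units)) {
    factors <- c("mg/L" = 1, "g/L" = 1000, "mg/dL" = 10)
    bad <- setdiff(units, names(factors))
    if (length(bad) > 0L) {
      stop("unknown unit(s): ", paste(bad, collapse = ", "),
           "; supported: ", paste(names(factors), collapse = ", "),
           call. = FALSE)
    }
    for (col in names(units)) {
      if (!col %in% required) {
        stop("units given for unknown concentration column: ", col,
             call. = FALSE)
      }
      cohort[[col]] <- cohort[[col]] * factors[[units[[col]]]]
    }
  }
  if ("ocmb_status" %in% names(cohort) &&
      !all(cohort$ocmb_status %in% c(0, 1, NA))) {
    stop("ocmb_status must be 0, 1 or NA", call. = FALSE)
  }
  cohort
}

#' Write a cohort CSV
#'
#' Writes the canonical cohort dialect read by [read_cohort()] (mg/L, header,
#' decimal point, UTF-8, no row names).
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Shared validation: strictly positive, finite, non-missing numeric input.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("'", name, "' must be numeric and non-empty", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("'", name, "' must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}
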