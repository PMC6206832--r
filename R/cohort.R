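# Cohort module: per-patient count records and the summary statistics
# printed in tumor-board pilot-study overview tables.

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics at position
#' \code{1 + (n - 1) p} (quantile type 7, the R default); missing values are
#' excluded first.
#'
#' @param values Numeric vector with at least one non-missing value.
#' @param na_policy Only \code{"exclude"} is supported.
#' @param type Quantile convention, passed to [stats::quantile()].
#' @return Named numeric vector \code{c(median = ..., iqr = ...)}.
#' @export
#' @examples
#' median_iqr(c(12, 19, 12, 7, 8, 7, 12, 10, 10, 11, 6))  # 10, 4.5
median_iqr <- function(values, na_policy = c("exclude"), type = 7) {
  na_policy <- match.arg(na_policy)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Read per-patient count records
#'
#' @param file TSV with columns patient_id, cohort, n_actionable,
#'   n_therapies_total, n_cancer_type_specific, n_off_label,
#'   n_investigational, n_lacking_benefit (\code{NA} allowed for counts not
#'   yet part of the workflow).
#' @return Data frame of patient records.
#' @export
read_patient_records <- function(file) {
  rec <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("patient_id", "cohort", "n_actionable", "n_therapies_total",
              "n_cancer_type_specific", "n_off_label", "n_investigational",
              "n_lacking_benefit")
  miss <- setdiff(needed, names(rec))
  if (length(miss) > 0) {
    stop("patient records lack column(s): ", paste(miss, collapse = ", "))
  }
  complete <- stats::complete.cases(rec[, c("n_therapies_total",
                                            "n_cancer_type_specific",
                                            "n_off_label",
                                            "n_investigational")])
  bad <- complete & (rec$n_therapies_total != rec$n_cancer_type_specific +
                       rec$n_off_label + rec$n_investigational)
  if (any(bad)) {
    stop("therapy section counts do not sum to the total for patient(s): ",
         paste(rec$patient_id[bad], collapse = ", "))
  }
  rec
}

#' Summarize a patient cohort
#'
#' Applies [median_iqr()] per count column (with NA exclusion) and reports
#' how many patients carried at least one actionable aberration.
#'
#' @param records Patient record data frame (see [read_patient_records()]).
#' @return A list of class \code{mtb_cohort_summary}: \code{n_patients},
#'   \code{n_actionable_patients}, \code{actionable_rate}, and a
#'   \code{columns} data frame of (median, iqr) per summarized column.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0) stop("records must be non-empty")
  cols <- c("n_actionable", "n_therapies_total", "n_cancer_type_specific",
            "n_off_label", "n_investigational", "n_lacking_benefit")
  stats_df <- do.call(rbind, lapply(cols, function(cl) {
    mi <- median_iqr(records[[cl]])
    data.frame(column = cl, median = unname(mi["median"]),
               iqr = unname(mi["iqr"]), stringsAsFactors = FALSE)
  }))
  n_act <- sum(records$n_actionable >= 1, na.rm = TRUE)
  structure(list(n_patients = nrow(records),
                 n_actionable_patients = n_act,
                 actionable_rate = n_act / nrow(records),
                 columns = stats_df),
            class = "mtb_cohort_summary")
}

#' @export
print.mtb_cohort_summary <- function(x, ...) {
  cat("Cohort of ", x$n_patients, " patients; ", x$n_actionable_patients,
      " with >=1 actionable aberration (",
      round(100 * x$actionable_rate), "%)\n", sep = "")
  for (i in seq_len(nrow(x$columns))) {
    cat(sprintf("  %-24s median %g (IQR %g)\n", x$columns$column[i],
                x$columns$median[i], x$columns$iqr[i]))
  }
  invisible(x)
}

#' Off-label plus investigational therapy count per patient
#'
#' Therapies beyond the approved standard of care for the patient's cancer
#' type: the sum of off-label and investigational recommendations.
#'
#' @param records Patient record data frame.
#' @return Integer vector, one value per patient.
#' @export
off_label_plus_investigational <- function(records) {
  records$n_off_label + records$n_investigational
}
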