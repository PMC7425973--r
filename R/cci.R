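#' Charlson comorbidity conditions and score
#'
#' The 15 Charlson conditions used as matching flags and (weighted) as the
#' time-dependent comorbidity score covariate. Malignancy categories are
#' excluded because all cases carry them by definition. Weights follow the
#' original Charlson scheme: 1 for most conditions, 2 for diabetes with
#' complications, paraplegia/hemiplegia and renal disease, 3 for
#' moderate/severe liver disease and 6 for AIDS.
#'
#' @return [cci_conditions()]: character vector of the 15 condition codes
#'   (used as `cci_<code>` claim columns); [cci_weights()]: named integer
#'   vector of weights.
#' @export
cci_conditions <- function() {
  c("mi", "chf", "pvd", "cvd", "dementia", "copd", "rheum", "ulcer",
    "mild_liver", "diabetes", "diabetes_comp", "paraplegia", "renal",
    "severe_liver", "aids")
}

#' @rdname cci_conditions
#' @export
cci_weights <- function() {
  w <- c(mi = 1L, chf = 1L, pvd = 1L, cvd = 1L, dementia = 1L, copd = 1L,
         rheum = 1L, ulcer = 1L, mild_liver = 1L, diabetes = 1L,
         diabetes_comp = 2L, paraplegia = 2L, renal = 2L, severe_liver = 3L,
         aids = 6L)
  w[cci_conditions()]
}

#' Weighted comorbidity score from condition flags
#'
#' @param flags A matrix or data frame with one column per condition, named
#'   `cci_<code>` (or bare codes), rows are patient-months or patients.
#' @return Numeric vector of weighted scores.
#' @export
cci_score <- function(flags) {
  flags <- as.data.frame(flags)
  codes <- cci_conditions()
  cols <- ifelse(paste0("cci_", codes) %in% names(flags),
                 paste0("cci_", codes), codes)
  missing <- cols[!cols %in% names(flags)]
  if (length(missing)) {
    stop("missing condition flag column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  w <- cci_weights()
  out <- numeric(nrow(flags))
  for (i in seq_along(codes)) {
    out <- out + w[[codes[i]]] * as.numeric(flags[[cols[i]]])
  }
  out
}

# column names for claim-panel flags
cci_columns <- function() paste0("cci_", cci_conditions())
tx_modalities <- function() {
  c("resection", "lrt", "tace", "tae", "sorafenib", "chemo", "radiotherapy")
}
tx_columns <- function() paste0("tx_", tx_modalities())
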