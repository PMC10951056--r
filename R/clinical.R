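#' Clinical record at one timepoint
#'
#' Serum and urine data for a patient at biopsy or six months after
#' treatment start. At least one proteinuria measure (24-h excretion, total
#' protein:creatinine ratio, or albumin:creatinine ratio) should be present
#' on records used for response classification.
#'
#' @param patient_id character scalar.
#' @param timepoint "biopsy" or "month6".
#' @param age_years age in years (> 0).
#' @param sex "male" or "female".
#' @param scr_umol_l serum creatinine, micromoles per litre (NA if not
#'   measured).
#' @param proteinuria_g24h measured 24-h protein excretion, g/day (NA if
#'   absent).
#' @param upcr_mg_mmol urinary total protein to creatinine ratio, mg/mmol
#'   (NA if absent).
#' @param acr_mg_mmol urinary albumin to creatinine ratio, mg/mmol (NA if
#'   absent).
#' @return object of class `clinical_record`.
#' @export
clinical_record <- function(patient_id, timepoint = c("biopsy", "month6"),
                            age_years, sex = c("male", "female"),
                            scr_umol_l = NA_real_,
                            proteinuria_g24h = NA_real_,
                            upcr_mg_mmol = NA_real_,
                            acr_mg_mmol = NA_real_) {
  timepoint <- match.arg(timepoint)
  sex <- match.arg(sex)
  if (!is.finite(age_years) || age_years <= 0)
    stop("age_years must be > 0", call. = FALSE)
  structure(list(patient_id = as.character(patient_id), timepoint = timepoint,
                 age_years = as.numeric(age_years), sex = sex,
                 scr_umol_l = as.numeric(scr_umol_l),
                 proteinuria_g24h = as.numeric(proteinuria_g24h),
                 upcr_mg_mmol = as.numeric(upcr_mg_mmol),
                 acr_mg_mmol = as.numeric(acr_mg_mmol)),
            class = "clinical_record")
}

UMOL_PER_MGDL <- 88.42  # creatinine unit conversion

#' CKD-EPI estimated glomerular filtration rate
#'
#' Creatinine-based eGFR from serum creatinine, age and sex. The default is
#' the 2021 race-free CKD-EPI refit:
#' eGFR = 142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age *
#' (1.012 if female), with k = 0.7 (female) / 0.9 (male) mg/dL and
#' a = -0.241 (female) / -0.302 (male). `version = "2009"` selects the
#' original coefficients (141, exponent -1.209, 0.993^age, 1.018 female
#' factor, a = -0.329/-0.411). Serum creatinine is taken in micromoles per
#' litre and converted to mg/dL by dividing by 88.42.
#'
#' The equation is not validated in children: ages below 18 are refused.
#'
#' @param scr_umol_l serum creatinine, micromoles per litre.
#' @param age_years age in years (>= 18).
#' @param sex "male" or "female".
#' @param version "2021" (default) or "2009".
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckd_epi <- function(scr_umol_l, age_years, sex = c("male", "female"),
                         version = c("2021", "2009")) {
  sex <- match.arg(sex)
  version <- match.arg(version)
  if (!is.finite(age_years)) stop("age_years must be given", call. = FALSE)
  if (age_years < 18)
    stop("CKD-EPI is not defined for pediatric patients (age < 18)",
         call. = FALSE)
  if (!is.finite(scr_umol_l) || scr_umol_l <= 0)
    stop("scr_umol_l must be > 0", call. = FALSE)
  scr <- scr_umol_l / UMOL_PER_MGDL
  female <- sex == "female"
  kappa <- if (female) 0.7 else 0.9
  if (version == "2021") {
    alpha <- if (female) -0.241 else -0.302
    142 * min(scr / kappa, 1)^alpha * max(scr / kappa, 1)^-1.200 *
      0.9938^age_years * (if (female) 1.012 else 1)
  } else {
    alpha <- if (female) -0.329 else -0.411
    141 * min(scr / kappa, 1)^alpha * max(scr / kappa, 1)^-1.209 *
      0.993^age_years * (if (female) 1.018 else 1)
  }
}

#' Daily protein excretion estimate
#'
#' Prefers the measured 24-h excretion; otherwise estimates g/day from the
#' total protein:creatinine ratio as UPCR / 100, the factor anchored by the
#' clinical equivalence of 350 mg/mmol and 3.5 g/day.
#'
#' @param record a [clinical_record()].
#' @return estimated protein excretion in g/day.
#' @export
proteinuria_g_per_day <- function(record) {
  stopifnot(inherits(record, "clinical_record"))
  if (is.finite(record$proteinuria_g24h)) return(record$proteinuria_g24h)
  if (is.finite(record$upcr_mg_mmol)) return(record$upcr_mg_mmol / 100)
  stop("no usable proteinuria measure for patient ", record$patient_id,
       call. = FALSE)
}

#' Classify treatment response at six months
#'
#' Remission ("responder"): proteinuria below 3.5 g/day (measured or
#' estimated from UPCR; strict inequality) with stable serum creatinine,
#' quantified as a month-6 value no more than `(1 + creatinine_stability_tol)`
#' times baseline (default tolerance 0.30). Fallbacks mirror the clinical
#' workflow: with only an ACR available, an ACR equivalent to < 0.5 g/day
#' (ACR < 50 mg/mmol) classifies as responder; with no proteinuria measure
#' at all, a serum creatinine rise above tolerance classifies as
#' non-responder. A month-6 record with neither proteinuria nor creatinine
#' is unclassifiable.
#'
#' @param biopsy_rec baseline [clinical_record()] (timepoint "biopsy").
#' @param month6_rec six-month [clinical_record()].
#' @param creatinine_stability_tol allowed fractional creatinine rise
#'   (default 0.30).
#' @return "responder" or "non_responder".
#' @export
classify_response <- function(biopsy_rec, month6_rec,
                              creatinine_stability_tol = 0.30) {
  stopifnot(inherits(biopsy_rec, "clinical_record"),
            inherits(month6_rec, "clinical_record"))
  if (biopsy_rec$patient_id != month6_rec$patient_id)
    stop("records belong to different patients", call. = FALSE)

  creat_stable <- NA
  if (is.finite(month6_rec$scr_umol_l) && is.finite(biopsy_rec$scr_umol_l))
    creat_stable <- month6_rec$scr_umol_l <=
      (1 + creatinine_stability_tol) * biopsy_rec$scr_umol_l

  has_prot <- is.finite(month6_rec$proteinuria_g24h) ||
    is.finite(month6_rec$upcr_mg_mmol)
  if (has_prot) {
    prot <- proteinuria_g_per_day(month6_rec)
    in_remission <- prot < 3.5 && !isFALSE(creat_stable)
    return(if (in_remission) "responder" else "non_responder")
  }
  if (is.finite(month6_rec$acr_mg_mmol))
    return(if (month6_rec$acr_mg_mmol < 50 && !isFALSE(creat_stable))
      "responder" else "non_responder")
  if (!is.na(creat_stable))
    return(if (creat_stable) "responder" else "non_responder")
  stop("patient ", month6_rec$patient_id,
       ": no proteinuria or creatinine at month 6; unclassifiable",
       call. = FALSE)
}

CLINICAL_COLUMNS <- c("patient_id", "timepoint", "age_years", "sex",
                      "scr_umol_l", "proteinuria_g24h", "upcr_mg_mmol",
                      "acr_mg_mmol")

#' Read clinical records from CSV
#'
#' @param path CSV with columns `patient_id, timepoint, age_years, sex,
#'   scr_umol_l, proteinuria_g24h, upcr_mg_mmol, acr_mg_mmol`; empty cells
#'   are absent measurements.
#' @return list of [clinical_record()] objects.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing))
    stop("clinical CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    clinical_record(df$patient_id[i], df$timepoint[i], df$age_years[i],
                    df$sex[i], df$scr_umol_l[i], df$proteinuria_g24h[i],
                    df$upcr_mg_mmol[i], df$acr_mg_mmol[i]))
}

#' Write clinical records to CSV
#'
#' @param records list of [clinical_record()] objects.
#' @param path output path.
#' @return invisibly, the data frame written.
#' @export
write_clinical <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id, timepoint = r$timepoint,
               age_years = r$age_years, sex = r$sex,
               scr_umol_l = r$scr_umol_l,
               proteinuria_g24h = r$proteinuria_g24h,
               upcr_mg_mmol = r$upcr_mg_mmol, acr_mg_mmol = r$acr_mg_mmol,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Classify every patient in a set of clinical records
#'
#' @param records list of [clinical_record()] objects containing a biopsy
#'   and a month6 record per patient.
#' @param creatinine_stability_tol passed to [classify_response()].
#' @return data frame with columns patient_id, label.
#' @export
classify_cohort <- function(records, creatinine_stability_tol = 0.30) {
  ids <- vapply(records, `[[`, character(1), "patient_id")
  tps <- vapply(records, `[[`, character(1), "timepoint")
  out <- lapply(unique(ids), function(pid) {
    b <- records[ids == pid & tps == "biopsy"]
    m <- records[ids == pid & tps == "month6"]
    if (length(m) != 1L)
      stop("patient ", pid, " needs exactly one month6 record", call. = FALSE)
    if (length(b) != 1L)
      stop("patient ", pid, " needs exactly one biopsy record", call. = FALSE)
    data.frame(patient_id = pid,
               label = classify_response(b[[1]], m[[1]],
                                         creatinine_stability_tol),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
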