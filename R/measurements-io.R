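#' Single glomerular profile measurement
#'
#' Bundles the raw quantities measured on one glomerular tuft profile in a
#' thin optical section: tuft profile area (sclerotic regions included),
#' semiquantitative sclerosis score, and the per-nucleus mean XY caliper
#' diameters of every podocyte nucleus identified in the profile, plus the
#' synaptopodin-positive (podocyte cytoplasm) area within the tuft.
#'
#' @param glomerulus_id character scalar identifier, unique within a biopsy.
#' @param tuft_area tuft profile area in square micrometres (> 0).
#' @param sclerosis_score integer sclerosis grade in 0..4 (0 = none,
#'   4 = global sclerosis occupying 76-100\% of the tuft).
#' @param nuclear_caliper_diameters numeric vector of per-nucleus mean
#'   XY caliper diameters in micrometres; length = podocyte nucleus count
#'   (may be length 0); all values > 0.
#' @param snp_area synaptopodin-positive area in square micrometres,
#'   0 <= snp_area <= tuft_area.
#' @return object of class `glomerulus_measurement`.
#' @export
glomerulus_measurement <- function(glomerulus_id, tuft_area, sclerosis_score,
                                   nuclear_caliper_diameters = numeric(),
                                   snp_area = 0) {
  stopifnot(length(glomerulus_id) == 1L, length(tuft_area) == 1L,
            length(sclerosis_score) == 1L, length(snp_area) == 1L)
  if (!is.finite(tuft_area) || tuft_area <= 0)
    stop("tuft_area must be a positive finite number", call. = FALSE)
  if (!is.finite(sclerosis_score) || sclerosis_score != as.integer(sclerosis_score) ||
      !(sclerosis_score %in% 0:4))
    stop("sclerosis_score must be an integer in 0..4", call. = FALSE)
  d <- as.numeric(nuclear_caliper_diameters)
  if (length(d) && (any(!is.finite(d)) || any(d <= 0)))
    stop("all nuclear caliper diameters must be positive", call. = FALSE)
  if (!is.finite(snp_area) || snp_area < 0 || snp_area > tuft_area)
    stop("snp_area must satisfy 0 <= snp_area <= tuft_area", call. = FALSE)
  structure(list(glomerulus_id = as.character(glomerulus_id),
                 tuft_area = as.numeric(tuft_area),
                 sclerosis_score = as.integer(sclerosis_score),
                 nuclear_caliper_diameters = d,
                 snp_area = as.numeric(snp_area)),
            class = "glomerulus_measurement")
}

#' Confocal optical configuration
#'
#' Excitation wavelength, immersion-medium refractive index and objective
#' numerical aperture, from which the effective optical section thickness
#' (axial resolution) is derived. The defaults are a DAPI channel imaged
#' with a 1.25-NA oil objective.
#'
#' @param excitation_wavelength_nm excitation wavelength in nanometres.
#' @param refractive_index refractive index of the immersion medium.
#' @param numerical_aperture objective numerical aperture; must be strictly
#'   less than the refractive index, otherwise the axial-resolution formula
#'   is undefined.
#' @return object of class `optical_config`.
#' @export
optical_config <- function(excitation_wavelength_nm = 405,
                           refractive_index = 1.515,
                           numerical_aperture = 1.25) {
  if (!all(is.finite(c(excitation_wavelength_nm, refractive_index,
                       numerical_aperture))) ||
      excitation_wavelength_nm <= 0 || refractive_index <= 0 ||
      numerical_aperture <= 0)
    stop("all optical parameters must be positive", call. = FALSE)
  if (numerical_aperture >= refractive_index)
    stop("numerical_aperture must be < refractive_index", call. = FALSE)
  structure(list(excitation_wavelength_nm = as.numeric(excitation_wavelength_nm),
                 refractive_index = as.numeric(refractive_index),
                 numerical_aperture = as.numeric(numerical_aperture)),
            class = "optical_config")
}

#' A patient's biopsy measurement set
#'
#' The unit of podometric estimation: all glomerular profiles measured on
#' one patient's biopsy section plus the optical configuration the section
#' was imaged with.
#'
#' @param patient_id character scalar.
#' @param glomeruli list of [glomerulus_measurement()] objects.
#' @param optics an [optical_config()].
#' @return object of class `biopsy_measurement`.
#' @export
biopsy_measurement <- function(patient_id, glomeruli, optics = optical_config()) {
  stopifnot(length(patient_id) == 1L, is.list(glomeruli))
  if (!all(vapply(glomeruli, inherits, logical(1), "glomerulus_measurement")))
    stop("glomeruli must all be glomerulus_measurement objects", call. = FALSE)
  if (!inherits(optics, "optical_config"))
    stop("optics must be an optical_config", call. = FALSE)
  ids <- vapply(glomeruli, `[[`, character(1), "glomerulus_id")
  if (anyDuplicated(ids))
    stop("duplicated glomerulus_id within biopsy ", patient_id, call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 glomeruli = glomeruli, optics = optics),
            class = "biopsy_measurement")
}

#' @export
print.biopsy_measurement <- function(x, ...) {
  cat(sprintf("<biopsy_measurement> patient %s: %d glomerular profiles\n",
              x$patient_id, length(x$glomeruli)))
  invisible(x)
}

n_glomeruli <- function(biopsy) length(biopsy$glomeruli)

glom_field <- function(biopsy, field)
  vapply(biopsy$glomeruli, `[[`, numeric(1), field)

all_diameters <- function(biopsy)
  unlist(lapply(biopsy$glomeruli, `[[`, "nuclear_caliper_diameters"),
         use.names = FALSE)

MEASUREMENT_COLUMNS <- c("patient_id", "glomerulus_id", "tuft_area_um2",
                         "sclerosis_score", "nuclear_caliper_diameters_um",
                         "snp_area_um2")
OPTICS_COLUMNS <- c("excitation_wavelength_nm", "refractive_index",
                    "numerical_aperture")

parse_diameter_cell <- function(cell) {
  cell <- trimws(as.character(cell))
  if (is.na(cell) || cell == "") return(numeric())
  as.numeric(strsplit(cell, ";", fixed = TRUE)[[1]])
}

format_diameter_cell <- function(d) paste(format(d, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = ";")

#' Read biopsy measurements from CSV
#'
#' Reads the per-(patient, glomerulus) measurement table. One comma-separated
#' dialect is supported: "." decimal, UTF-8, header required, per-nucleus
#' caliper diameters as a ";"-joined list in one cell. Optics come either
#' from a sidecar CSV (`optics_path`) with one row per patient (or a single
#' row applied to all) or from optics columns embedded in the table.
#'
#' @param path path to the measurements CSV.
#' @param optics_path optional path to an optics sidecar CSV with columns
#'   `excitation_wavelength_nm`, `refractive_index`, `numerical_aperture`
#'   and optionally `patient_id`.
#' @return named list of [biopsy_measurement()] objects, one per patient, in
#'   first-appearance order.
#' @export
read_measurements <- function(path, optics_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing))
    stop("measurements CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  score_raw <- df$sclerosis_score
  score_num <- suppressWarnings(as.numeric(score_raw))
  bad <- which(!is.finite(score_num) | score_num != floor(score_num) |
                 score_num < 0 | score_num > 4)
  if (length(bad))
    stop("invalid sclerosis_score at row ", bad[1], " (value '",
         score_raw[bad[1]], "'): must be an integer 0..4", call. = FALSE)

  optics_for <- resolve_optics(df, optics_path)
  split_idx <- split(seq_len(nrow(df)), factor(df$patient_id,
                                               levels = unique(df$patient_id)))
  lapply(split_idx, function(rows) {
    pid <- df$patient_id[rows[1]]
    gloms <- lapply(rows, function(i) {
      glomerulus_measurement(
        glomerulus_id = df$glomerulus_id[i],
        tuft_area = as.numeric(df$tuft_area_um2[i]),
        sclerosis_score = score_num[i],
        nuclear_caliper_diameters = parse_diameter_cell(
          df$nuclear_caliper_diameters_um[i]),
        snp_area = as.numeric(df$snp_area_um2[i]))
    })
    biopsy_measurement(pid, gloms, optics_for(pid))
  })
}

resolve_optics <- function(df, optics_path) {
  if (!is.null(optics_path)) {
    odf <- utils::read.csv(optics_path, stringsAsFactors = FALSE)
    missing <- setdiff(OPTICS_COLUMNS, names(odf))
    if (length(missing))
      stop("optics CSV is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if ("patient_id" %in% names(odf) && nrow(odf) > 1) {
      function(pid) {
        row <- odf[odf$patient_id == pid, , drop = FALSE]
        if (nrow(row) != 1)
          stop("optics CSV has ", nrow(row), " rows for patient ", pid,
               call. = FALSE)
        optical_config(row$excitation_wavelength_nm, row$refractive_index,
                       row$numerical_aperture)
      }
    } else {
      shared <- optical_config(odf$excitation_wavelength_nm[1],
                               odf$refractive_index[1],
                               odf$numerical_aperture[1])
      function(pid) shared
    }
  } else if (all(OPTICS_COLUMNS %in% names(df))) {
    function(pid) {
      i <- which(df$patient_id == pid)[1]
      optical_config(as.numeric(df$excitation_wavelength_nm[i]),
                     as.numeric(df$refractive_index[i]),
                     as.numeric(df$numerical_aperture[i]))
    }
  } else {
    stop("no optics given: provide optics_path or embed ",
         paste(OPTICS_COLUMNS, collapse = ", "), " columns", call. = FALSE)
  }
}

#' Write biopsy measurements to CSV
#'
#' Inverse of [read_measurements()]: writing then reading is the identity on
#' valid records (diameters kept to full double precision).
#'
#' @param biopsies list of [biopsy_measurement()] objects.
#' @param path output CSV path for measurements.
#' @param optics_path output CSV path for the optics sidecar (one row per
#'   patient).
#' @return invisibly, the measurement data frame written.
#' @export
write_measurements <- function(biopsies, path, optics_path) {
  rows <- do.call(rbind, lapply(biopsies, function(b) {
    data.frame(
      patient_id = b$patient_id,
      glomerulus_id = vapply(b$glomeruli, `[[`, character(1), "glomerulus_id"),
      tuft_area_um2 = format(glom_field(b, "tuft_area"), digits = 17,
                             trim = TRUE, scientific = FALSE),
      sclerosis_score = vapply(b$glomeruli, `[[`, integer(1), "sclerosis_score"),
      nuclear_caliper_diameters_um = vapply(
        b$glomeruli, function(g) format_diameter_cell(g$nuclear_caliper_diameters),
        character(1)),
      snp_area_um2 = format(glom_field(b, "snp_area"), digits = 17,
                            trim = TRUE, scientific = FALSE),
      stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  odf <- do.call(rbind, lapply(biopsies, function(b) {
    data.frame(patient_id = b$patient_id,
               excitation_wavelength_nm = b$optics$excitation_wavelength_nm,
               refractive_index = b$optics$refractive_index,
               numerical_aperture = b$optics$numerical_aperture,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(odf, optics_path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}

#' Apply the glomerulus-count inclusion rule
#'
#' Biopsies whose section contains six or fewer glomerular profiles are
#' excluded from podometric estimation (the boundary is inclusive: 6 is
#' excluded, 7 is included). Other clinical exclusion criteria are upstream
#' curation and not computable from measurement data.
#'
#' @param biopsies list of [biopsy_measurement()] objects.
#' @param min_glomeruli exclusion boundary; biopsies with
#'   `<= min_glomeruli` profiles are excluded (default 6).
#' @return list with elements `included` (list of biopsies, untouched) and
#'   `excluded` (character vector of patient ids).
#' @export
apply_inclusion_filter <- function(biopsies, min_glomeruli = 6L) {
  n <- vapply(biopsies, n_glomeruli, integer(1))
  keep <- n > min_glomeruli
  list(included = biopsies[keep],
       excluded = unname(vapply(biopsies[!keep], `[[`, character(1),
                                "patient_id")))
}
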