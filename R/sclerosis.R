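#' Sclerosis grade counts
#'
#' Numbers of glomeruli per semiquantitative sclerosis grade 0..4 (grade 4
#' = global sclerosis).
#'
#' @param n0,n1,n2,n3,n4 non-negative integer counts.
#' @return object of class `sclerosis_counts`.
#' @export
sclerosis_counts <- function(n0 = 0, n1 = 0, n2 = 0, n3 = 0, n4 = 0) {
  n <- c(n0 = n0, n1 = n1, n2 = n2, n3 = n3, n4 = n4)
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(lapply(n, as.integer), class = "sclerosis_counts")
}

#' Sclerosis counts from a biopsy's scores
#'
#' @param biopsy a [biopsy_measurement()].
#' @return a [sclerosis_counts()] tabulating the profiles' grades.
#' @export
count_sclerosis_scores <- function(biopsy) {
  stopifnot(inherits(biopsy, "biopsy_measurement"))
  s <- vapply(biopsy$glomeruli, `[[`, integer(1), "sclerosis_score")
  tab <- tabulate(s + 1L, nbins = 5L)
  sclerosis_counts(tab[1], tab[2], tab[3], tab[4], tab[5])
}

counts_total <- function(counts) with(counts, n0 + n1 + n2 + n3 + n4)

#' Glomerulosclerotic index
#'
#' GSI = (1*N1 + 2*N2 + 3*N3 + 4*N4) / (N0 + N1 + N2 + N3 + N4): the
#' count-weighted mean sclerosis grade, in \[0, 4\].
#'
#' @param counts a [sclerosis_counts()] with at least one glomerulus.
#' @return dimensionless GSI.
#' @export
gsi <- function(counts) {
  stopifnot(inherits(counts, "sclerosis_counts"))
  total <- counts_total(counts)
  if (total < 1L) stop("GSI undefined for zero glomeruli", call. = FALSE)
  with(counts, (1 * n1 + 2 * n2 + 3 * n3 + 4 * n4) / total)
}

#' Percentage of glomeruli with global sclerosis
#'
#' Grade 4 is synonymous with global sclerosis, so this is 100 * N4 / total.
#'
#' @inheritParams gsi
#' @return percentage in \[0, 100\].
#' @export
pct_global <- function(counts) {
  stopifnot(inherits(counts, "sclerosis_counts"))
  total <- counts_total(counts)
  if (total < 1L) stop("undefined for zero glomeruli", call. = FALSE)
  100 * counts$n4 / total
}

#' Percentage of glomeruli with FSGS (segmental) lesions
#'
#' By default counts grades 1-3 (segmental lesions), with global sclerosis
#' reported separately; `include_global = TRUE` adds grade 4.
#'
#' @inheritParams gsi
#' @param include_global also count grade-4 (globally sclerotic) glomeruli.
#' @return percentage in \[0, 100\].
#' @export
pct_fsgs <- function(counts, include_global = FALSE) {
  stopifnot(inherits(counts, "sclerosis_counts"))
  total <- counts_total(counts)
  if (total < 1L) stop("undefined for zero glomeruli", call. = FALSE)
  num <- with(counts, n1 + n2 + n3 + if (include_global) n4 else 0L)
  100 * num / total
}

#' Default threshold set for response classification
#'
#' Podocyte count 216 (inclusive, "216 or less"), GSI 1 (strictly greater),
#' 20 percent global sclerosis (strictly greater), 50 percent FSGS lesions
#' (strictly greater).
#'
#' @return named list of the four thresholds.
#' @export
default_thresholds <- function() {
  list(podocytes = 216, gsi = 1, pct_global = 20, pct_fsgs = 50)
}

#' Threshold classifiers for treatment response
#'
#' Flags a patient's biopsy against the four indicator thresholds. Boundary
#' semantics follow the quoted definitions: `low_podocyte` is inclusive
#' (count <= 216), the other three are strict (> 1, > 20, > 50).
#'
#' @param podocytes_per_tuft real-valued podocyte number per tuft.
#' @param gsi glomerulosclerotic index.
#' @param pct_global percent globally sclerotic glomeruli.
#' @param pct_fsgs percent glomeruli with FSGS lesions.
#' @param thresholds list as from [default_thresholds()].
#' @return named logical vector `low_podocyte`, `gsi_gt_1`, `global_gt_20`,
#'   `fsgs_gt_50`.
#' @export
classify_thresholds <- function(podocytes_per_tuft, gsi, pct_global, pct_fsgs,
                                thresholds = default_thresholds()) {
  c(low_podocyte = podocytes_per_tuft <= thresholds$podocytes,
    gsi_gt_1 = gsi > thresholds$gsi,
    global_gt_20 = pct_global > thresholds$pct_global,
    fsgs_gt_50 = pct_fsgs > thresholds$pct_fsgs)
}

#' Sclerosis summary for a biopsy
#'
#' @param biopsy a [biopsy_measurement()].
#' @param podocytes_per_tuft the biopsy's estimated podocyte number (used
#'   only for the `low_podocyte` flag; may be NA to skip).
#' @param include_global passed to [pct_fsgs()].
#' @param thresholds passed to [classify_thresholds()].
#' @return one-row data frame: patient_id, gsi, pct_global, pct_fsgs and the
#'   four 0/1 flag columns.
#' @export
compute_sclerosis <- function(biopsy, podocytes_per_tuft = NA_real_,
                              include_global = FALSE,
                              thresholds = default_thresholds()) {
  counts <- count_sclerosis_scores(biopsy)
  g <- gsi(counts)
  pg <- pct_global(counts)
  pf <- pct_fsgs(counts, include_global = include_global)
  flags <- classify_thresholds(podocytes_per_tuft, g, pg, pf, thresholds)
  data.frame(patient_id = biopsy$patient_id, gsi = g, pct_global = pg,
             pct_fsgs = pf,
             low_podocyte = as.integer(flags[["low_podocyte"]]),
             gsi_gt_1 = as.integer(flags[["gsi_gt_1"]]),
             global_gt_20 = as.integer(flags[["global_gt_20"]]),
             fsgs_gt_50 = as.integer(flags[["fsgs_gt_50"]]),
             stringsAsFactors = FALSE)
}
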