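#' Reference joint cohort reconstructed from published aggregate counts
#'
#' Rebuilds, patient by patient, the unique 35-record joint distribution of
#' immunoscore class x mrTRG-1 status x pCR that is consistent with the
#' published marginal counts of a LARC total-neoadjuvant-therapy trial
#' cohort: 35 patients, 15 pCR, 23 IS-high, 14 with mrTRG 1, and 9 in the
#' combined high-IS/mrTRG-1 stratum of whom 6 achieved pCR. Margin
#' bookkeeping forces the remaining cells: (high, TRG!=1) 14 with 5 pCR,
#' (low, TRG1) 5 with 1 pCR, (low, TRG!=1) 7 with 3 pCR.
#'
#' Records carry stages consistent with their endpoint: pCR patients have
#' ypT0/ypN0 and pTRG 0; non-pCR patients ypT2/ypN1 and pTRG 2. Patients
#' without complete radiologic response are assigned mrTRG 2
#' deterministically. Densities and follow-up are absent (the source
#' reports no patient-level values); `is_class` is carried as a
#' precomputed column, which [score_cohort()] preserves when densities are
#' unavailable.
#'
#' @return data frame of 35 patient records in the cohort-file schema plus
#'   an `is_class` column.
#' @export
fixture_joint_cohort <- function() {
  cells <- data.frame(
    is_class = c("high", "high", "low", "low"),
    mrtrg    = c(1L, 2L, 1L, 2L),
    n        = c(9L, 14L, 5L, 7L),
    n_pcr    = c(6L, 5L, 1L, 3L),
    stringsAsFactors = FALSE
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], data.frame(
      is_class = rep(is_class, n),
      mrtrg = rep(mrtrg, n),
      pcr_flag = rep(c(TRUE, FALSE), c(n_pcr, n - n_pcr)),
      stringsAsFactors = FALSE))
  }))
  n <- nrow(rows)
  df <- data.frame(
    patient_id = sprintf("F%02d", seq_len(n)),
    ct_stage = "T3",
    cn_stage = "N1",
    ypt_stage = ifelse(rows$pcr_flag, "T0", "T2"),
    ypn_stage = ifelse(rows$pcr_flag, "N0", "N1"),
    rt_post_stage = ifelse(rows$mrtrg == 1L, "T0", "T2"),
    rn_post_stage = ifelse(rows$mrtrg == 1L, "N0", "N1"),
    mrtrg = rows$mrtrg,
    ptrg = ifelse(rows$pcr_flag, 0L, 2L),
    cd3_ct = NA_real_, cd3_im = NA_real_,
    cd8_ct = NA_real_, cd8_im = NA_real_,
    grade = NA_integer_,
    dfs_months = NA_real_, dfs_event = NA_integer_,
    os_months = NA_real_, os_event = NA_integer_,
    is_class = rows$is_class,
    stringsAsFactors = FALSE
  )
  df
}

#' Printed pCR x NAR-category contingency tables
#'
#' The two published 2x3 tables cross-classifying pCR status against the
#' low/intermediate/high NAR category, stored exactly as printed. Note the
#' printed tables imply 13 pCR patients while the joint cohort counts 15 —
#' an internal inconsistency of the published record that is preserved
#' here, not repaired (see the package vignette). The pathologic table also
#' contains one pCR patient in the intermediate category, which the NAR
#' formula cannot produce for baseline cT 2-4; it too is stored as printed.
#'
#' @return list of two integer matrices, `pathologic` (rows non-pCR/pCR =
#'   4,9,9 / 12,1,0) and `radiologic` (10,6,6 / 8,5,0), with NAR category
#'   columns.
#' @export
fixture_nar_tables <- function() {
  cats <- c("low", "intermediate", "high")
  path <- matrix(c(4L, 9L, 9L, 12L, 1L, 0L), nrow = 2, byrow = TRUE,
                 dimnames = list(pcr = c("non_pcr", "pcr"), nar = cats))
  rad <- matrix(c(10L, 6L, 6L, 8L, 5L, 0L), nrow = 2, byrow = TRUE,
                dimnames = list(pcr = c("non_pcr", "pcr"), nar = cats))
  list(pathologic = path, radiologic = rad)
}

#' Printed tumor-grade counts by pCR status
#'
#' Tumor differentiation grade (1 well, 2 moderate, 3 poor) tabulated
#' against pCR status as published: among pCR patients 12 were grade 2 and
#' 1 grade 3; among non-pCR patients 1, 20 and 1 were grades 1-3. The
#' implied pCR denominator is 13, again at odds with the 15 pCR of the
#' joint counts; stored as printed.
#'
#' @return integer matrix with rows `non_pcr`/`pcr` and columns
#'   `grade1`-`grade3`.
#' @export
fixture_grade_table <- function() {
  matrix(c(1L, 20L, 1L, 0L, 12L, 1L), nrow = 2, byrow = TRUE,
         dimnames = list(pcr = c("non_pcr", "pcr"),
                         grade = c("grade1", "grade2", "grade3")))
}
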