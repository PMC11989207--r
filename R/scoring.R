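#' Cohort-internal percentile ranks of cell densities
#'
#' Converts raw cell densities (cells/mm^2) of one marker-region across a
#' cohort into percentile ranks using the Hazen plotting position,
#' `100 * (rank - 0.5) / n`, with mid-ranks for ties. The convention is
#' symmetric, keeps ranks away from 0 and 100, and is standard for small
#' cohorts. Only the ordering of densities matters: the result is invariant
#' under any positive affine transformation of the input.
#'
#' Missing values are excluded from the reference set (`n` counts non-missing
#' values) and propagate as missing in the output.
#'
#' @param x numeric vector of non-negative densities for one marker-region.
#' @return numeric vector of percentiles in (0, 100), aligned with `x`.
#' @examples
#' percentile_ranks(c(10, 20, 30, 40))
#' @export
percentile_ranks <- function(x) {
  if (length(x) == 0L) stop("density vector is empty", call. = FALSE)
  obs <- !is.na(x)
  if (!any(obs)) stop("density vector is all missing", call. = FALSE)
  v <- x[obs]
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("densities must be finite and non-negative", call. = FALSE)
  }
  out <- rep(NA_real_, length(x))
  out[obs] <- 100 * (rank(v, ties.method = "average") - 0.5) / length(v)
  out
}

#' Immunoscore from four marker-region density percentiles
#'
#' The immunoscore (IS) is the arithmetic mean of the four density
#' percentiles CD3 (tumor core), CD3 (invasive margin), CD8 (tumor core)
#' and CD8 (invasive margin), dichotomized at a cutoff (default 62): a mean
#' percentile at or above the cutoff is classed `"high"`, below it `"low"`.
#'
#' All arguments are vectorized; a record missing any of the four
#' percentiles gets a missing mean and class.
#'
#' @param p_cd3_ct,p_cd3_im,p_cd8_ct,p_cd8_im numeric percentiles in
#'   \[0, 100\].
#' @param cutoff percentile cutoff separating high from low (default 62).
#' @return data frame with the four input percentiles, `mean_percentile`,
#'   and `is_class` (`"high"`/`"low"`).
#' @examples
#' immunoscore(80, 70, 60, 62)
#' @export
immunoscore <- function(p_cd3_ct, p_cd3_im, p_cd8_ct, p_cd8_im, cutoff = 62) {
  p <- cbind(p_cd3_ct, p_cd3_im, p_cd8_ct, p_cd8_im)
  v <- p[!is.na(p)]
  if (any(!is.finite(v)) || any(v < 0) || any(v > 100)) {
    stop("percentiles must lie in [0, 100]", call. = FALSE)
  }
  if (!is.finite(cutoff) || cutoff < 0 || cutoff > 100) {
    stop("cutoff must lie in [0, 100]", call. = FALSE)
  }
  mean_p <- rowMeans(p)
  cls <- ifelse(is.na(mean_p), NA_character_,
                ifelse(mean_p >= cutoff, "high", "low"))
  data.frame(p_cd3_ct = p[, 1], p_cd3_im = p[, 2],
             p_cd8_ct = p[, 3], p_cd8_im = p[, 4],
             mean_percentile = mean_p, is_class = cls,
             stringsAsFactors = FALSE)
}

check_stage_int <- function(x, lo, hi, what) {
  bad <- !is.na(x) & !(x %in% lo:hi)
  if (any(bad)) {
    stop(what, " out of encoded range ", lo, "-", hi, ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(x)
}

nar_value <- function(t_base, t_post, n_post) {
  (5 * n_post - 3 * (t_base - t_post) + 12)^2 / 9.61
}

#' Categorize a NAR score value
#'
#' Low is below 8, intermediate from 8 to 16 inclusive, high above 16.
#' Attainable NAR values are of the form k^2 / 9.61 with integer k, so the
#' boundaries 8 and 16 are never hit exactly in practice; the inclusive
#' assignment fixes the contract regardless.
#'
#' @param value non-negative numeric NAR score value(s).
#' @return character vector `"low"`/`"intermediate"`/`"high"`.
#' @export
categorize_nar <- function(value) {
  v <- value[!is.na(value)]
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("NAR value must be finite and non-negative", call. = FALSE)
  }
  ifelse(is.na(value), NA_character_,
         ifelse(value < 8, "low",
                ifelse(value <= 16, "intermediate", "high")))
}

#' Pathologic neoadjuvant rectal (NAR) score
#'
#' The NAR score is a surrogate endpoint combining the baseline clinical
#' T stage with the post-treatment pathologic T and N stages:
#' \deqn{NAR = \frac{(5\,pN - 3\,(cT - pT) + 12)^2}{9.61}}
#' The inner term is non-negative over the encoded stage domain
#' (cT, pT in 0-4; pN in 0-2), so the score lies in \[0, 34^2/9.61\].
#'
#' @param ct integer baseline clinical T stage, 0-4 (see
#'   [encode_t_stage()]).
#' @param ypt integer post-treatment pathologic T stage, 0-4.
#' @param ypn integer post-treatment pathologic N stage, 0-2.
#' @return data frame with `value`, `category` (via [categorize_nar()]) and
#'   `variant = "pathologic"`.
#' @examples
#' nar_pathologic(3, 0, 0)   # deep response: 9/9.61, low
#' nar_pathologic(3, 3, 1)   # no T regression, nodal residual: high
#' @export
nar_pathologic <- function(ct, ypt, ypn) {
  ct  <- check_stage_int(ct,  0, 4, "clinical T stage")
  ypt <- check_stage_int(ypt, 0, 4, "pathologic T stage")
  ypn <- check_stage_int(ypn, 0, 2, "pathologic N stage")
  v <- nar_value(ct, ypt, ypn)
  data.frame(value = v, category = categorize_nar(v),
             variant = "pathologic", stringsAsFactors = FALSE)
}

#' Radiologic neoadjuvant rectal (NAR) score
#'
#' Same arithmetic as [nar_pathologic()] with post-treatment MRI stages in
#' place of pathologic stages:
#' \deqn{NAR_{rad} = \frac{(5\,cN_{post} - 3\,(cT_{pre} - cT_{post}) + 12)^2}{9.61}}
#'
#' @param ct_pre integer pre-treatment clinical (MRI) T stage, 0-4.
#' @param ct_post integer post-treatment MRI T stage, 0-4.
#' @param cn_post integer post-treatment MRI N stage, 0-2.
#' @return data frame with `value`, `category` and `variant = "radiologic"`.
#' @export
nar_radiologic <- function(ct_pre, ct_post, cn_post) {
  ct_pre  <- check_stage_int(ct_pre,  0, 4, "pre-treatment T stage")
  ct_post <- check_stage_int(ct_post, 0, 4, "post-treatment T stage")
  cn_post <- check_stage_int(cn_post, 0, 2, "post-treatment N stage")
  v <- nar_value(ct_pre, ct_post, cn_post)
  data.frame(value = v, category = categorize_nar(v),
             variant = "radiologic", stringsAsFactors = FALSE)
}

#' Combined immunoscore and mrTRG stratum
#'
#' Patients with both a high immunoscore and complete radiologic response
#' (mrTRG 1) form the stratum of interest (`"is_high_and_trg1"`); everyone
#' else is `"other"`. Either input missing gives a missing stratum.
#'
#' @param is_class character, `"high"` or `"low"`.
#' @param mrtrg integer MRI tumor regression grade, 1-5.
#' @return character vector `"is_high_and_trg1"`/`"other"`.
#' @export
combined_stratum <- function(is_class, mrtrg) {
  cls <- as.character(is_class)
  bad <- !is.na(cls) & !(cls %in% c("high", "low"))
  if (any(bad)) {
    stop("is_class must be 'high' or 'low': ",
         paste(unique(cls[bad]), collapse = ", "), call. = FALSE)
  }
  mrtrg <- check_mrtrg(mrtrg)
  ifelse(is.na(cls) | is.na(mrtrg), NA_character_,
         ifelse(cls == "high" & mrtrg == 1L, "is_high_and_trg1", "other"))
}
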