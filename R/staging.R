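#' Encode a T-stage label as its integer stage
#'
#' Collapses AJCC/UICC 8th-edition T-stage text codes to the integer stage
#' used by the NAR score arithmetic. Substage letters (e.g. the depth-of-
#' invasion subclasses `"T3a"`-`"T3d"`) are discarded; `"Tis"` maps to 0.
#'
#' @param label character vector of stage codes (`"T0"`-`"T4"`, optional
#'   substage letter a-d). `NA` or empty cells stay missing.
#' @return integer vector in 0-4, `NA` where the input was missing.
#' @examples
#' encode_t_stage(c("T3b", "T0", "T4a"))
#' @export
encode_t_stage <- function(label) {
  lab <- trimws(as.character(label))
  out <- rep(NA_integer_, length(lab))
  miss <- is.na(lab) | lab == ""
  if (all(miss)) return(out)
  v <- lab[!miss]
  is_tis <- toupper(v) == "TIS"
  ok <- is_tis | grepl("^[Tt][0-4][a-dA-D]?$", v)
  if (any(!ok)) {
    stop("malformed T-stage label(s): ",
         paste(unique(v[!ok]), collapse = ", "), call. = FALSE)
  }
  val <- integer(length(v))
  val[!is_tis] <- as.integer(substr(v[!is_tis], 2L, 2L))
  out[!miss] <- val
  out
}

#' Encode an N-stage label as its integer stage
#'
#' `N0` -> 0, `N1`/`N1a`-`N1c` -> 1, `N2`/`N2a`-`N2b` -> 2.
#'
#' @param label character vector of nodal stage codes.
#' @return integer vector in 0-2, `NA` where the input was missing.
#' @examples
#' encode_n_stage(c("N0", "N1c", "N2b"))
#' @export
encode_n_stage <- function(label) {
  lab <- trimws(as.character(label))
  out <- rep(NA_integer_, length(lab))
  miss <- is.na(lab) | lab == ""
  if (all(miss)) return(out)
  v <- lab[!miss]
  ok <- grepl("^[Nn][0-2][a-cA-C]?$", v)
  if (any(!ok)) {
    stop("malformed N-stage label(s): ",
         paste(unique(v[!ok]), collapse = ", "), call. = FALSE)
  }
  out[!miss] <- as.integer(substr(v, 2L, 2L))
  out
}

check_ptrg <- function(ptrg) {
  bad <- !is.na(ptrg) & !(ptrg %in% 0:3)
  if (any(bad)) {
    stop("pTRG grade out of range 0-3: ",
         paste(unique(ptrg[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(ptrg)
}

check_mrtrg <- function(mrtrg) {
  bad <- !is.na(mrtrg) & !(mrtrg %in% 1:5)
  if (any(bad)) {
    stop("mrTRG grade out of range 1-5: ",
         paste(unique(mrtrg[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(mrtrg)
}

#' Derive pathologic complete response (pCR)
#'
#' pCR is defined as no residual tumor cells in the resection specimen
#' (pathologic tumor regression grade 0) together with node-negative
#' pathologic stage (ypN0). A missing grade or nodal stage yields a missing
#' endpoint, never `FALSE`: per-analysis denominators are complete-case.
#'
#' @param ptrg integer pathologic tumor regression grade, 0-3.
#' @param ypn character post-treatment pathologic N-stage label.
#' @return logical vector; `NA` where either input is missing.
#' @examples
#' derive_pcr(c(0, 0, 1), c("N0", "N1", "N0"))
#' @export
derive_pcr <- function(ptrg, ypn) {
  ptrg <- check_ptrg(ptrg)
  n <- encode_n_stage(ypn)
  out <- ptrg == 0L & n == 0L
  out[is.na(ptrg) | is.na(n)] <- NA   # never let FALSE absorb a missing input
  out
}

#' Derive near-pathologic complete response
#'
#' Near-pCR means at most minimal residual disease: pTRG 0 or 1 (fewer than
#' 10% residual tumor cells).
#'
#' @param ptrg integer pathologic tumor regression grade, 0-3.
#' @return logical vector; `NA` where the grade is missing.
#' @export
derive_near_pcr <- function(ptrg) {
  ptrg <- check_ptrg(ptrg)
  ptrg <= 1L
}

#' Complete radiologic response from the MRI tumor regression grade
#'
#' mrTRG 1 denotes complete radiologic response (no evidence of tumor on
#' post-treatment MRI); grades 2-5 do not.
#'
#' @param mrtrg integer MRI tumor regression grade, 1-5.
#' @return logical vector; `NA` where the grade is missing.
#' @export
is_radiologic_complete <- function(mrtrg) {
  mrtrg <- check_mrtrg(mrtrg)
  mrtrg == 1L
}
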