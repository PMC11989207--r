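#' Cross-tabulate two categorical variables
#'
#' Builds an r x c contingency table of joint counts, dropping pairs with a
#' missing entry in either variable (complete-case).
#'
#' @param a,b equal-length vectors of category labels (character or factor).
#' @param a_name,b_name dimension names for the table.
#' @return an integer matrix of counts with row labels from `a` and column
#'   labels from `b`.
#' @examples
#' crosstab(c("pCR", "pCR", "non"), c("low", "low", "high"))
#' @export
crosstab <- function(a, b, a_name = "a", b_name = "b") {
  if (length(a) != length(b)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no complete pairs to tabulate", call. = FALSE)
  af <- if (is.factor(a)) droplevels(factor(a[keep], levels = levels(a))) else factor(a[keep])
  bf <- if (is.factor(b)) droplevels(factor(b[keep], levels = levels(b))) else factor(b[keep])
  tab <- table(af, bf, dnn = c(a_name, b_name))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c(a_name, b_name)
  m
}

#' Exact test of independence for 2x2 and 2x3 tables
#'
#' Fisher's exact test, generalized to 2x3 tables after Freeman and Halton,
#' by full enumeration: every table with the observed row and column margins
#' is generated, each is assigned its multivariate hypergeometric
#' probability under the null,
#' \deqn{P(T) = \frac{\prod_i R_i!\ \prod_j C_j!}{N!\ \prod_{ij} T_{ij}!},}
#' and the two-sided p-value is the total probability of tables no more
#' probable than the observed one (a relative tie tolerance of 1e-9 guards
#' the comparison against floating-point noise). For 2x2 tables this is the
#' classic two-sided Fisher test.
#'
#' All-zero rows and columns are removed before testing, so a 2x3 table
#' whose third column is empty gives exactly the 2x2 result on the first
#' two columns. If fewer than two nonzero rows or columns remain, the test
#' is degenerate: p = 1 with a warning.
#'
#' @param tab matrix of non-negative integer counts, at most 2x3 (a 3x2
#'   table is transposed internally).
#' @return an object of class `"exact_test"`: list with `p_value`,
#'   `observed_table_prob`, and `n_tables_enumerated`.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2, 2))
#' @export
fisher_exact <- function(tab) {
  m <- as.matrix(tab)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("table must contain non-negative integer counts", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  # drop empty margins first: they carry no information
  m2 <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m2) < 2 || ncol(m2) < 2) {
    warning("degenerate margin: fewer than two nonzero rows/columns; p = 1",
            call. = FALSE)
    return(structure(list(p_value = 1, observed_table_prob = 1,
                          n_tables_enumerated = 1L),
                     class = "exact_test"))
  }
  if (nrow(m2) > ncol(m2)) m2 <- t(m2)
  if (nrow(m2) != 2 || ncol(m2) > 3) {
    stop("only 2x2 and 2x3 tables are supported (got ",
         nrow(m), "x", ncol(m), ")", call. = FALSE)
  }
  rs <- rowSums(m2); cs <- colSums(m2); N <- sum(m2)
  log_k <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  lp_obs <- log_k - sum(lfactorial(m2))
  # enumerate first rows; second row follows from the column margins
  grid <- expand.grid(lapply(cs, function(cj) 0:cj))
  grid <- grid[rowSums(grid) == rs[1], , drop = FALSE]
  lp <- log_k - apply(grid, 1, function(a) {
    sum(lfactorial(a)) + sum(lfactorial(cs - a))
  })
  p <- sum(exp(lp[lp <= lp_obs + log1p(1e-9)]))
  structure(list(p_value = min(p, 1), observed_table_prob = exp(lp_obs),
                 n_tables_enumerated = nrow(grid)),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat("Exact test of independence (full enumeration)\n")
  cat(sprintf("  p-value: %.6g  (observed table prob %.6g; %d tables enumerated)\n",
              x$p_value, x$observed_table_prob, x$n_tables_enumerated))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Independent-sample mean comparison with unequal variances (Welch) and
#' Welch-Satterthwaite degrees of freedom; two-sided p-value.
#'
#' @param x,y numeric samples, each of size at least 2.
#' @return list with `t`, `df`, and `p`.
#' @export
t_test_independent <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  res <- tryCatch(
    stats::t.test(x, y, var.equal = FALSE),
    error = function(e) {
      stop("t-test not defined (degenerate variance): ",
           conditionMessage(e), call. = FALSE)
    })
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
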