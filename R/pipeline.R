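#' Score every patient of a cohort
#'
#' Attaches all per-patient scores to a cohort table: cohort-internal
#' density percentiles per marker-region, the immunoscore mean percentile
#' and class, pathologic and radiologic NAR scores with categories, the
#' pCR/near-pCR endpoints, and the combined immunoscore x mrTRG stratum.
#' Missing inputs yield missing outputs (complete-case handling happens in
#' the downstream analyses, not here).
#'
#' If no patient carries a complete set of the four densities, the
#' immunoscore step is skipped with a warning; an existing `is_class`
#' column (as in the reference fixture, where only the class is published)
#' is preserved in that case.
#'
#' @param records cohort data frame (see [read_cohort()] for the schema).
#' @param cutoff immunoscore cutoff percentile (default 62).
#' @return the input data frame with score columns appended.
#' @export
score_cohort <- function(records, cutoff = 62) {
  df <- records
  for (col in setdiff(cohort_columns, names(df))) {
    df[[col]] <- rep(NA, nrow(df))
  }
  dens_cols <- c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im")
  have_dens <- rowSums(is.na(df[dens_cols])) == 0
  if (any(have_dens)) {
    pr <- lapply(df[dens_cols], percentile_ranks)
    is_res <- immunoscore(pr$cd3_ct, pr$cd3_im, pr$cd8_ct, pr$cd8_im,
                          cutoff = cutoff)
    df$p_cd3_ct <- pr$cd3_ct; df$p_cd3_im <- pr$cd3_im
    df$p_cd8_ct <- pr$cd8_ct; df$p_cd8_im <- pr$cd8_im
    df$is_mean_percentile <- is_res$mean_percentile
    df$is_class <- is_res$is_class
  } else {
    warning("no complete CD3/CD8 density sets; immunoscore computation skipped",
            call. = FALSE)
    if (!"is_class" %in% names(df)) df$is_class <- NA_character_
    if (!"is_mean_percentile" %in% names(df)) {
      df$is_mean_percentile <- NA_real_
    }
  }
  ct <- encode_t_stage(df$ct_stage)
  ypt <- encode_t_stage(df$ypt_stage)
  ypn <- encode_n_stage(df$ypn_stage)
  rt <- encode_t_stage(df$rt_post_stage)
  rn <- encode_n_stage(df$rn_post_stage)
  path_ok <- !is.na(ct) & !is.na(ypt) & !is.na(ypn)
  df$nar_path <- NA_real_; df$nar_path_cat <- NA_character_
  if (any(path_ok)) {
    res <- nar_pathologic(ct[path_ok], ypt[path_ok], ypn[path_ok])
    df$nar_path[path_ok] <- res$value
    df$nar_path_cat[path_ok] <- res$category
  }
  rad_ok <- !is.na(ct) & !is.na(rt) & !is.na(rn)
  df$nar_rad <- NA_real_; df$nar_rad_cat <- NA_character_
  if (any(rad_ok)) {
    res <- nar_radiologic(ct[rad_ok], rt[rad_ok], rn[rad_ok])
    df$nar_rad[rad_ok] <- res$value
    df$nar_rad_cat[rad_ok] <- res$category
  }
  df$pcr <- derive_pcr(df$ptrg, df$ypn_stage)
  df$near_pcr <- derive_near_pcr(df$ptrg)
  df$combined_stratum <- combined_stratum(df$is_class, df$mrtrg)
  df
}

prop_block <- function(count, denom) {
  pct <- if (denom > 0) 100 * count / denom else NA_real_
  list(count = count, denominator = denom, pct = pct)
}

rate_among <- function(outcome, subset) {
  ok <- !is.na(outcome) & !is.na(subset) & subset
  prop_block(sum(outcome[ok]), sum(ok))
}

nar_levels <- c("low", "intermediate", "high")

#' Summarize a pCR x NAR-category table
#'
#' Row percentages and the exact (Freeman-Halton) test of independence for
#' a 2x3 pCR-by-NAR-category table.
#'
#' @param tab 2x3 integer matrix, rows non-pCR/pCR, columns NAR categories.
#' @return list with `counts`, `row_pct` (percentages within each pCR
#'   row), and `exact` ([fisher_exact()] result).
#' @export
summarize_nar_table <- function(tab) {
  m <- as.matrix(tab)
  rp <- sweep(m, 1, rowSums(m), "/") * 100
  list(counts = m, row_pct = rp, exact = fisher_exact(m))
}

#' Tumor-grade breakdown by pCR status
#'
#' Row percentages of the grade distribution within pCR and non-pCR
#' patients. If `expected_pcr_total` is supplied and disagrees with the
#' table's pCR denominator, the discrepancy is surfaced as a warning — the
#' published record reports 15 pCR patients overall but a grade breakdown
#' covering only 13.
#'
#' @param grade_tab integer matrix with rows `non_pcr`/`pcr` and grade
#'   columns (see [fixture_grade_table()]).
#' @param expected_pcr_total optional pCR count to reconcile against.
#' @return list with `counts` and `row_pct`.
#' @export
grade_breakdown <- function(grade_tab, expected_pcr_total = NULL) {
  m <- as.matrix(grade_tab)
  if (!is.null(expected_pcr_total)) {
    got <- sum(m["pcr", ])
    if (got != expected_pcr_total) {
      warning(sprintf(paste0("grade table pCR denominator (%d) disagrees ",
                             "with the reported pCR count (%d)"),
                      got, expected_pcr_total), call. = FALSE)
    }
  }
  list(counts = m, row_pct = sweep(m, 1, rowSums(m), "/") * 100)
}

km_group_summary <- function(times, events, group, levels) {
  ok <- !is.na(times) & !is.na(events) & !is.na(group)
  if (!any(ok)) return(NULL)
  times <- times[ok]; events <- events[ok]; group <- group[ok]
  horizon <- max(times)
  present <- levels[levels %in% unique(group)]
  per_group <- lapply(present, function(g) {
    sel <- group == g
    list(group = g, n = sum(sel), n_events = sum(events[sel]),
         event_free = event_free_proportion(times[sel], events[sel], horizon))
  })
  names(per_group) <- present
  lr <- if (length(present) >= 2) {
    logrank_test(lapply(present, function(g) {
      sel <- group == g
      list(times = times[sel], events = events[sel])
    }))
  } else NULL
  list(horizon = horizon, groups = per_group, logrank = lr)
}

#' Run the full response-scoring analysis of a cohort
#'
#' Computes the analysis report: prevalence of pCR, mrTRG 1 and high
#' immunoscore; conditional pCR rates within the mrTRG-1, IS-high and
#' combined strata; pCR x NAR contingency tables (pathologic and
#' radiologic) with exact Freeman-Halton p-values; Kaplan-Meier event-free
#' summaries at the end of observed follow-up and log-rank tests by NAR
#' category for DFS and OS; and the near-pCR DFS comparison. Every block
#' uses its own complete-case denominator and reports it; a block whose
#' denominator is empty is marked not computable and the run continues.
#'
#' Percentages are carried as exact ratios; the text report prints them
#' rounded to one decimal next to their counts, and an internal consistency
#' check asserts each percentage matches its count ratio.
#'
#' @param records cohort data frame, raw or already scored (raw input is
#'   passed through [score_cohort()] first).
#' @param cutoff immunoscore cutoff percentile used when scoring raw input.
#' @return an object of class `"analysis_report"`.
#' @export
analyze <- function(records, cutoff = 62) {
  df <- if (!"pcr" %in% names(records)) score_cohort(records, cutoff = cutoff)
        else records
  n <- nrow(df)

  prevalence <- list(
    pcr = prop_block(sum(df$pcr, na.rm = TRUE), sum(!is.na(df$pcr))),
    mrtrg1 = prop_block(sum(df$mrtrg == 1, na.rm = TRUE),
                        sum(!is.na(df$mrtrg))),
    is_high = prop_block(sum(df$is_class == "high", na.rm = TRUE),
                         sum(!is.na(df$is_class)))
  )
  conditional_pcr <- list(
    mrtrg1 = rate_among(df$pcr, df$mrtrg == 1),
    is_high = rate_among(df$pcr, df$is_class == "high"),
    combined = rate_among(df$pcr, df$combined_stratum == "is_high_and_trg1")
  )

  pcr_lab <- ifelse(is.na(df$pcr), NA_character_,
                    ifelse(df$pcr, "pcr", "non_pcr"))
  nar_block <- function(cat_col) {
    cats <- factor(df[[cat_col]], levels = nar_levels)
    ok <- !is.na(pcr_lab) & !is.na(cats)
    if (!any(ok)) return(NULL)
    tab <- crosstab(factor(pcr_lab, levels = c("non_pcr", "pcr")), cats,
                    a_name = "pcr", b_name = "nar")
    summarize_nar_table(tab)
  }
  nar_tables <- list(pathologic = nar_block("nar_path_cat"),
                     radiologic = nar_block("nar_rad_cat"))

  survival <- list(
    dfs_by_nar_path = km_group_summary(df$dfs_months, df$dfs_event,
                                       df$nar_path_cat, nar_levels),
    os_by_nar_path = km_group_summary(df$os_months, df$os_event,
                                      df$nar_path_cat, nar_levels),
    dfs_by_nar_rad = km_group_summary(df$dfs_months, df$dfs_event,
                                      df$nar_rad_cat, nar_levels),
    os_by_nar_rad = km_group_summary(df$os_months, df$os_event,
                                     df$nar_rad_cat, nar_levels)
  )
  near_lab <- ifelse(is.na(df$near_pcr), NA_character_,
                     ifelse(df$near_pcr, "near_pcr", "not_near_pcr"))
  near_pcr_dfs <- km_group_summary(df$dfs_months, df$dfs_event, near_lab,
                                   c("near_pcr", "not_near_pcr"))

  rep <- structure(list(n = n, prevalence = prevalence,
                        conditional_pcr = conditional_pcr,
                        nar_tables = nar_tables, survival = survival,
                        near_pcr_dfs = near_pcr_dfs),
                   class = "analysis_report")
  check_report_consistency(rep)
  rep
}

# every reported percentage must equal its count ratio (to within rounding
# noise); guards against drift between the counts and percents we emit
check_report_consistency <- function(rep) {
  blocks <- c(rep$prevalence, rep$conditional_pcr)
  for (b in blocks) {
    if (b$denominator > 0) {
      stopifnot(abs(b$pct - 100 * b$count / b$denominator) < 1e-9)
    }
  }
  invisible(rep)
}

fmt_prop <- function(b, label) {
  if (b$denominator == 0) {
    sprintf("  %-28s not computable (empty denominator)", label)
  } else {
    sprintf("  %-28s %d/%d (%.1f%%)", label, b$count, b$denominator, b$pct)
  }
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Render an analysis report as text
#'
#' @param rep an `"analysis_report"` from [analyze()].
#' @return character vector of report lines.
#' @export
report_text <- function(rep) {
  out <- c(sprintf("Response-scoring analysis report (n = %d)", rep$n),
           "", "Prevalence:",
           fmt_prop(rep$prevalence$pcr, "pCR"),
           fmt_prop(rep$prevalence$mrtrg1, "mrTRG 1"),
           fmt_prop(rep$prevalence$is_high, "IS high"),
           "", "pCR rate within stratum:",
           fmt_prop(rep$conditional_pcr$mrtrg1, "mrTRG 1"),
           fmt_prop(rep$conditional_pcr$is_high, "IS high"),
           fmt_prop(rep$conditional_pcr$combined, "IS high & mrTRG 1"))
  for (variant in c("pathologic", "radiologic")) {
    tb <- rep$nar_tables[[variant]]
    out <- c(out, "", sprintf("pCR x %s NAR category:", variant))
    if (is.null(tb)) {
      out <- c(out, "  not computable (no complete cases)")
      next
    }
    for (r in rownames(tb$counts)) {
      cells <- sprintf("%s %d (%.1f%%)", colnames(tb$counts),
                       tb$counts[r, ], tb$row_pct[r, ])
      out <- c(out, sprintf("  %-8s %s", r, paste(cells, collapse = ", ")))
    }
    out <- c(out, sprintf("  exact test p = %.4g (%d tables enumerated)",
                          tb$exact$p_value, tb$exact$n_tables_enumerated))
  }
  surv_line <- function(s, label) {
    if (is.null(s)) {
      return(sprintf("  %-18s not computable", label))
    }
    cells <- vapply(s$groups, function(g) {
      sprintf("%s %.1f%% (n=%d)", g$group, 100 * g$event_free, g$n)
    }, character(1))
    p_txt <- if (is.null(s$logrank)) "" else
      sprintf("; log-rank p = %.4g", s$logrank$p)
    sprintf("  %-18s at %.1f mo: %s%s", label, s$horizon,
            paste(cells, collapse = ", "), p_txt)
  }
  out <- c(out, "", "Event-free proportions at end of follow-up:",
           surv_line(rep$survival$dfs_by_nar_path, "DFS x path. NAR"),
           surv_line(rep$survival$os_by_nar_path, "OS x path. NAR"),
           surv_line(rep$survival$dfs_by_nar_rad, "DFS x rad. NAR"),
           surv_line(rep$survival$os_by_nar_rad, "OS x rad. NAR"),
           surv_line(rep$near_pcr_dfs, "DFS x near-pCR"))
  out
}

#' Render an analysis report as JSON
#'
#' @param rep an `"analysis_report"` from [analyze()].
#' @return JSON string with the same fields as the report object.
#' @export
report_json <- function(rep) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attr(x, "class") <- NULL
    }
    x
  }
  jsonlite::toJSON(strip(unclass(rep)), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE, na = "null")
}
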