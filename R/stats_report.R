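#' One-way between-subjects ANOVA with partial eta squared
#'
#' Standard between/within sum-of-squares decomposition (via [stats::aov()]),
#' upper-tail F probability, and the effect size
#' `eta_p2 = SS_between / (SS_between + SS_within)`. Degrees of freedom are
#' computed from the data supplied, never assumed.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values), or
#'   a data.frame with columns `value` and `group`.
#' @return An `anova_result`: `F`, `df_between`, `df_within`, `p`, `eta_p2`,
#'   `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    df <- data.frame(value = groups$value, group = factor(groups$group))
  } else {
    if (length(groups) < 2) stop("need at least two groups")
    if (any(vapply(groups, length, integer(1)) < 2))
      stop("each group needs at least two values")
    nm <- if (is.null(names(groups))) seq_along(groups) else names(groups)
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(nm, vapply(groups, length, integer(1)))))
  }
  tab <- summary(stats::aov(value ~ group, data = df))[[1]]
  ssb <- tab["group", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  df1 <- tab["group", "Df"]
  df2 <- tab["Residuals", "Df"]
  if (ssb + ssw <= 0)
    stop("zero total variance: F undefined")
  Fstat <- (ssb / df1) / (ssw / df2)
  structure(list(F = Fstat, df_between = df1, df_within = df2,
                 p = f_upper_tail(Fstat, df1, df2),
                 eta_p2 = ssb / (ssb + ssw),
                 ss_between = ssb, ss_within = ssw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g, eta_p2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$eta_p2))
  invisible(x)
}

#' Upper tail of the F distribution
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Degrees of freedom.
#' @return `P(F' >= F)`.
#' @export
f_upper_tail <- function(F, df1, df2) {
  if (any(F < 0) || df1 <= 0 || df2 <= 0) stop("invalid F or degrees of freedom")
  stats::pf(F, df1, df2, lower.tail = FALSE)
}

#' Shapiro-Wilk normality screen
#'
#' Reports per-group normality p-values (never used to gate the ANOVA).
#'
#' @param groups Named list of numeric vectors.
#' @return Named vector of p-values.
#' @export
normality_screen <- function(groups) {
  vapply(groups, function(g) stats::shapiro.test(g)$p.value, numeric(1))
}

#' Per-feature group-comparison report
#'
#' Runs a one-way ANOVA per feature column of a subject-level table and
#' returns F, p and partial eta squared, plus the normality screen.
#'
#' @param df data.frame with a `condition` column and numeric feature columns.
#' @param features Feature column names (default: all numeric columns except
#'   `condition`).
#' @return data.frame: feature, group means, F, df, p, eta_p2, shapiro p.
#' @export
stats_report <- function(df, features = NULL) {
  if (is.null(features))
    features <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "condition")
  conds <- levels(factor(df$condition))
  rows <- lapply(features, function(f) {
    groups <- split(df[[f]], df$condition)
    a <- one_way_anova(groups)
    means <- vapply(groups, mean, numeric(1))
    sw <- tryCatch(min(normality_screen(groups)), error = function(e) NA_real_)
    out <- data.frame(feature = f, F = a$F, df1 = a$df_between,
                      df2 = a$df_within, p = a$p, eta_p2 = a$eta_p2,
                      shapiro_min_p = sw)
    for (cn in conds) out[[paste0("mean_", cn)]] <- means[[cn]]
    out
  })
  do.call(rbind, rows)
}

#' Write a stats report as JSON and Markdown
#'
#' @param report A [stats_report()] data.frame.
#' @param path_json,path_md Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_stats_report <- function(report, path_json = NULL, path_md = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(report, path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(path_md)) {
    hdr <- paste0("| ", paste(names(report), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(report)), collapse = "|"), "|")
    rows <- vapply(seq_len(nrow(report)), function(i) {
      paste0("| ", paste(vapply(report[i, ], function(x)
        if (is.numeric(x)) sprintf("%.4g", x) else as.character(x),
        character(1)), collapse = " | "), " |")
    }, character(1))
    writeLines(c(hdr, sep, rows), path_md)
  }
  invisible(report)
}
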