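# Two-group time-course comparison: per-day group means +/- SD and a
# two-sided pooled-variance Student's t-test at alpha = 0.05, with the
# figure-style significance tiers. No multiple-testing correction is applied
# across days or variables, matching the study design this emulates.

significance_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Compare the two arms for one variable at one imaging day
#'
#' Classical (pooled-variance) two-sample Student's t with
#' `n1 + n2 - 2` degrees of freedom, two-sided; SDs are sample (n-1)
#' standard deviations. The t statistic is `(mean_control - mean_fasting)`
#' over the pooled standard error. Degenerate inputs: zero pooled variance
#' with equal means gives `t = 0, p = 1`; zero pooled variance with unequal
#' means is flagged `degenerate` (`p = 0`).
#'
#' @param table study table (one row per subject x day) with columns
#'   `subject_id`, `group`, `day` and the variable.
#' @param variable column name to compare.
#' @param day imaging day.
#' @return one-row data frame: variable, day, per-group mean and SD, `t`,
#'   two-sided `p`, significance `tier` (`ns`, `*`, `**`, `***`) and a
#'   `degenerate` flag.
#' @export
compare_groups <- function(table, variable, day) {
  stopifnot(variable %in% names(table))
  x <- table[[variable]][table$day == day & table$group == "control"]
  y <- table[[variable]][table$day == day & table$group == "fasting"]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    stop("need >= 2 subjects per group at day ", day,
         " (control ", n1, ", fasting ", n2, ")")
  }
  s2p <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  degenerate <- FALSE
  if (s2p == 0) {
    if (mean(x) == mean(y)) {
      tval <- 0
      p <- 1
    } else {
      degenerate <- TRUE
      tval <- sign(mean(x) - mean(y)) * Inf
      p <- 0
    }
  } else {
    tval <- (mean(x) - mean(y)) / sqrt(s2p * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tval), df = n1 + n2 - 2)
  }
  data.frame(variable = variable, day = day,
             mean_control = mean(x), sd_control = stats::sd(x),
             mean_fasting = mean(y), sd_fasting = stats::sd(y),
             t = tval, p = p, tier = significance_tier(p),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Per-day group comparisons for every variable (time-course report)
#'
#' One [compare_groups()] row per (variable, imaging day), ordered by day
#' within variable; the tabular counterpart of the study's time-course
#' figures. Days on which a group is missing (fewer than two subjects) are
#' skipped with a warning.
#'
#' @param table study table, one row per subject x day.
#' @param variables variables to compare (default: all morphometry
#'   columns).
#' @return data frame of comparisons.
#' @export
timecourse_report <- function(table,
                              variables = c("bmd", "mineral_content",
                                            "volume", "cortical_thickness",
                                            "body_height", "body_width",
                                            "min_moment", "polar_moment")) {
  days <- sort(unique(table$day))
  if (length(days) == 0L) stop("study table covers no imaging day")
  rows <- list()
  for (v in variables) {
    for (d in days) {
      n1 <- sum(table$day == d & table$group == "control")
      n2 <- sum(table$day == d & table$group == "fasting")
      if (n1 < 2L || n2 < 2L) {
        warning("day ", d, " skipped for ", v, ": a group is missing")
        next
      }
      rows[[length(rows) + 1L]] <- compare_groups(table, v, d)
    }
  }
  do.call(rbind, rows)
}

#' Write a time-course report as CSV
#'
#' @param report data frame from [timecourse_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_report <- function(report, path) {
  stopifnot(is.data.frame(report), nrow(report) > 0L)
  out <- report
  for (cn in c("mean_control", "sd_control", "mean_fasting", "sd_fasting",
               "t", "p")) {
    out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
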