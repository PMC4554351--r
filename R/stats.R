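#' Normality-gated paired comparison
#'
#' Compares two paired samples with the paired t-test when the paired
#' differences look normal, and with the Wilcoxon signed-rank test otherwise.
#' The gate is a Shapiro-Wilk test on the differences at `alpha_normality`
#' (Shapiro-Wilk needs 3-5000 values with nonzero spread; outside that the
#' gate cannot run and the rank test is used).  Both tests are two-sided.
#' The Wilcoxon test uses the exact null distribution when at most 25
#' nonzero differences are present and the normal approximation with
#' continuity correction above that.
#'
#' Identical samples (all differences zero) are degenerate: no test can
#' reject, so `p = 1` is returned with `degenerate = TRUE`.
#'
#' @param values_a,values_b equal-length numeric vectors (length >= 2), the
#'   per-patient metric under two plans; pairing is positional.
#' @param label optional label carried into the result.
#' @param alpha_normality significance level of the Shapiro-Wilk gate.
#' @return An object of class `paired_comparison`: `label`, `test_used`
#'   (`"paired-t"` or `"wilcoxon"`), `statistic`, `p_value`, `n`, means and
#'   SDs of both arms, `mean_diff`, `shapiro_p`, `significant` (p < 0.05)
#'   and `degenerate`.
#' @examples
#' set.seed(1)
#' a <- rnorm(20, 50, 5)
#' paired_compare(a + rnorm(20, 1), a)
#' @export
paired_compare <- function(values_a, values_b, label = "",
                           alpha_normality = 0.05) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  n <- length(values_a)
  if (n != length(values_b))
    stop("paired samples must have equal length", call. = FALSE)
  if (n < 2L)
    stop("paired comparison needs at least 2 pairs", call. = FALSE)
  if (anyNA(values_a) || anyNA(values_b))
    stop("paired samples must not contain missing values", call. = FALSE)
  d <- values_a - values_b

  res <- list(label = label, n = n,
              mean_a = mean(values_a), sd_a = stats::sd(values_a),
              mean_b = mean(values_b), sd_b = stats::sd(values_b),
              mean_diff = mean(d), shapiro_p = NA_real_,
              degenerate = FALSE)

  if (all(d == 0)) {
    res$test_used <- "wilcoxon"
    res$statistic <- 0
    res$p_value <- 1
    res$degenerate <- TRUE
  } else {
    if (n >= 3L && n <= 5000L && stats::sd(d) > 0)
      res$shapiro_p <- stats::shapiro.test(d)$p.value
    use_t <- !is.na(res$shapiro_p) && res$shapiro_p >= alpha_normality
    if (use_t) {
      tt <- stats::t.test(values_a, values_b, paired = TRUE)
      res$test_used <- "paired-t"
      res$statistic <- unname(tt$statistic)
      res$p_value <- tt$p.value
    } else {
      n_nz <- sum(d != 0)
      wt <- suppressWarnings(
        stats::wilcox.test(values_a, values_b, paired = TRUE,
                           exact = n_nz <= 25, correct = TRUE))
      res$test_used <- "wilcoxon"
      res$statistic <- unname(wt$statistic)
      res$p_value <- wt$p.value
    }
  }
  res$significant <- res$p_value < 0.05
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison>%s n = %d: %.3g +/- %.3g vs %.3g +/- %.3g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n, x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g%s%s\n", x$test_used,
              x$statistic, x$p_value,
              if (x$significant) " *" else "",
              if (x$degenerate) " (degenerate: identical samples)" else ""))
  invisible(x)
}

#' Summarise per-patient nodal metrics across a cohort
#'
#' Takes the long per-patient table produced by the pipeline (columns
#' `patient`, `plan`, `volume`, `metric`, `value`) and emits the cohort
#' summary: mean +/- SD of each metric per nodal volume and plan, plus the
#' paired comparisons IMRT vs 3D-CRT and IMRT_norm vs 3D-CRT for every
#' volume/metric combination.  TCP rows are expected (and reported) as the
#' mean of per-patient TCPs — by Jensen's inequality this is not the TCP of
#' the mean EUD, so the two summary columns cannot be derived from each
#' other.  The summary is invariant to patient ordering.
#'
#' @param per_patient long-format data frame; every patient must have a
#'   value for every plan x volume x metric combination present in the data.
#' @param plans plan labels expected per patient.
#' @return A list of class `cohort_summary`: `summary` (volume, metric,
#'   plan, n, mean, sd, small_n) and `tests` (volume, metric, comparison,
#'   test_used, statistic, p_value, significant).  With a single patient,
#'   SDs are reported as 0 and flagged via `small_n`.
#' @export
summarize_cohort <- function(per_patient,
                             plans = c("IMRT", "IMRT_norm", "3D-CRT")) {
  req <- c("patient", "plan", "volume", "metric", "value")
  if (!is.data.frame(per_patient) || !all(req %in% names(per_patient)))
    stop("`per_patient` needs columns patient, plan, volume, metric, value",
         call. = FALSE)
  df <- per_patient[per_patient$plan %in% plans, req]
  if (anyNA(df$value))
    stop("validation error: missing metric values", call. = FALSE)
  patients <- sort(unique(df$patient))
  volumes <- sort(unique(df$volume))
  metrics <- sort(unique(df$metric))

  # completeness: every patient x plan x volume x metric exactly once
  key <- interaction(df$patient, df$plan, df$volume, df$metric, drop = FALSE)
  expected <- expand.grid(patient = patients, plan = plans, volume = volumes,
                          metric = metrics, stringsAsFactors = FALSE)
  ekey <- interaction(expected$patient, expected$plan, expected$volume,
                      expected$metric, drop = FALSE)
  gaps <- expected[!(ekey %in% key), , drop = FALSE]
  if (nrow(gaps) > 0L) {
    show <- utils::head(sprintf("%s/%s/%s/%s", gaps$patient, gaps$plan,
                                gaps$volume, gaps$metric), 10L)
    stop(sprintf("validation error: incomplete patient records (%d gap(s)): %s",
                 nrow(gaps), paste(show, collapse = "; ")), call. = FALSE)
  }
  if (any(duplicated(key)))
    stop("validation error: duplicated patient/plan/volume/metric rows",
         call. = FALSE)

  small_n <- length(patients) < 2L
  if (small_n)
    warning("single-patient cohort: SDs reported as 0, no paired tests",
            call. = FALSE)

  summary_df <- do.call(rbind, lapply(volumes, function(vol) {
    do.call(rbind, lapply(metrics, function(met) {
      do.call(rbind, lapply(plans, function(pl) {
        v <- df$value[df$volume == vol & df$metric == met & df$plan == pl]
        data.frame(volume = vol, metric = met, plan = pl,
                   n = length(v), mean = mean(v),
                   sd = if (length(v) < 2L) 0 else stats::sd(v),
                   small_n = small_n, stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(summary_df) <- NULL

  tests_df <- NULL
  if (!small_n) {
    comparisons <- list(c("IMRT", "3D-CRT"), c("IMRT_norm", "3D-CRT"))
    comparisons <- Filter(function(cp) all(cp %in% plans), comparisons)
    tests_df <- do.call(rbind, lapply(volumes, function(vol) {
      do.call(rbind, lapply(metrics, function(met) {
        do.call(rbind, lapply(comparisons, function(cp) {
          sub <- df[df$volume == vol & df$metric == met, ]
          sub <- sub[order(sub$patient), ]
          a <- sub$value[sub$plan == cp[1]]
          b <- sub$value[sub$plan == cp[2]]
          pc <- paired_compare(a, b, label = sprintf("%s %s", vol, met))
          data.frame(volume = vol, metric = met,
                     comparison = paste(cp, collapse = " vs "),
                     test_used = pc$test_used, statistic = pc$statistic,
                     p_value = pc$p_value, significant = pc$significant,
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
    rownames(tests_df) <- NULL
  }

  structure(list(summary = summary_df, tests = tests_df),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Cohort summary (mean +/- SD):\n")
  s <- x$summary
  s$value <- sprintf("%.*f +/- %.*f", digits, s$mean, digits, s$sd)
  print(s[, c("volume", "metric", "plan", "n", "value")], row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nPaired tests:\n")
    t <- x$tests
    t$p_value <- signif(t$p_value, 3)
    print(t, row.names = FALSE)
  }
  invisible(x)
}
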