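test_that("identical samples are degenerate: p = 1, never significant", {
  a <- c(1, 2, 3, 4, 5)
  res <- paired_compare(a, a)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_true(res$degenerate)
  expect_equal(res$test_used, "wilcoxon")
})

test_that("normal differences route to a paired t-test matching the textbook formula", {
  set.seed(101)
  b <- stats::rnorm(41, 50, 5)
  a <- b + stats::rnorm(41, 0.5, 1)
  res <- paired_compare(a, b)
  d <- a - b
  expect_gte(res$shapiro_p, 0.05)          # gate chose normality
  expect_equal(res$test_used, "paired-t")
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = length(d) - 1)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
})

test_that("strongly non-normal differences route to the Wilcoxon signed-rank test", {
  set.seed(202)
  b <- rep(0, 41)
  a <- exp(stats::rnorm(41, 0, 1.5))       # heavily right-skewed differences
  expect_lt(stats::shapiro.test(a - b)$p.value, 0.05)  # oracle for the gate
  res <- paired_compare(a, b)
  expect_equal(res$test_used, "wilcoxon")
})

test_that("exact Wilcoxon p-value matches full sign-flip enumeration at small n", {
  set.seed(303)
  d <- c(0.8, -0.3, 1.9, 2.4, -1.1, 0.6, 3.2, 1.4)
  a <- d; b <- rep(0, length(d))
  # force the rank route regardless of the normality gate
  res <- paired_compare(a, b, alpha_normality = 2)
  expect_equal(res$test_used, "wilcoxon")
  # oracle: enumerate all 2^n sign assignments of the ranked |d|
  r <- rank(abs(d))
  n <- length(d)
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_lower <- mean(v_all <= v_obs)
  p_upper <- mean(v_all >= v_obs)
  p_oracle <- min(1, 2 * min(p_lower, p_upper))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("cohort summaries report means/SDs and paired tests per volume and metric", {
  plans <- c("IMRT", "IMRT_norm", "3D-CRT")
  vols <- c("LN_all_el", "LN_adj_el")
  mets <- c("Dmean", "EUD", "TCP")
  set.seed(9)
  base <- expand.grid(patient = sprintf("p%02d", 1:8), plan = plans,
                      volume = vols, metric = mets,
                      stringsAsFactors = FALSE)
  base$value <- stats::runif(nrow(base), 10, 60)
  # inject a known effect: IMRT_norm exactly 2 Gy below 3D-CRT everywhere
  for (v in vols) for (m in mets) {
    ref <- base$value[base$plan == "3D-CRT" & base$volume == v & base$metric == m]
    base$value[base$plan == "IMRT_norm" & base$volume == v & base$metric == m] <-
      ref - 2
  }
  out <- summarize_cohort(base)
  s <- out$summary
  expect_equal(nrow(s), length(plans) * length(vols) * length(mets))
  row <- s[s$volume == "LN_all_el" & s$metric == "EUD" & s$plan == "3D-CRT", ]
  ref <- base$value[base$plan == "3D-CRT" & base$volume == "LN_all_el" &
                      base$metric == "EUD"]
  expect_equal(row$mean, mean(ref))
  expect_equal(row$sd, stats::sd(ref))
  norm_tests <- out$tests[out$tests$comparison == "IMRT_norm vs 3D-CRT", ]
  expect_true(all(norm_tests$significant))             # constant -2 Gy shift

  # permutation invariance over input rows
  shuffled <- base[sample(nrow(base)), ]
  out2 <- summarize_cohort(shuffled)
  expect_equal(out2$summary, out$summary)
  expect_equal(out2$tests, out$tests)

  # identical plans per patient: degenerate p = 1
  same <- base
  for (v in vols) for (m in mets) {
    ref <- same$value[same$plan == "3D-CRT" & same$volume == v & same$metric == m]
    for (pl in c("IMRT", "IMRT_norm"))
      same$value[same$plan == pl & same$volume == v & same$metric == m] <- ref
  }
  out3 <- summarize_cohort(same)
  expect_true(all(out3$tests$p_value == 1))
  expect_false(any(out3$tests$significant))
})

test_that("incomplete or single-patient cohorts are handled explicitly", {
  df <- expand.grid(patient = c("p01", "p02"),
                    plan = c("IMRT", "IMRT_norm", "3D-CRT"),
                    volume = "LN_all_el", metric = "EUD",
                    stringsAsFactors = FALSE)
  df$value <- 30
  expect_error(summarize_cohort(df[-1, ]), "incomplete patient records")

  one <- df[df$patient == "p01", ]
  expect_warning(res <- summarize_cohort(one), "single-patient")
  expect_true(all(res$summary$sd == 0))
  expect_true(all(res$summary$small_n))
  expect_null(res$tests)
})
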