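test_that("plan invariants: fraction lattice and the 110 Gy cap", {
  p <- rt_plan("IMRT", 70)
  expect_equal(p$n_fractions, 35L)
  expect_error(rt_plan("IMRT", 71), "multiple")
  expect_error(rt_plan("IMRT", 112), "110 Gy cap")
  expect_error(rt_plan("SBRT", 70))
})

test_that("default constraint set encodes the normal-tissue limits", {
  cs <- default_constraints()
  expect_equal(length(unique(cs$id)), 7)               # 7 rules, one an OR pair
  expect_equal(length(unique(cs$structure)), 4)
  expect_equal(nrow(cs), 8)                            # 8 atomic predicates
  get <- function(st, m, x = NA) {
    r <- cs[cs$structure == st & cs$metric == m &
              (is.na(x) | (!is.na(cs$x) & cs$x == x)), ]
    r$limit
  }
  expect_equal(get("lung", "Vx", 20), 35)
  expect_equal(get("lung", "Dmean"), 20)
  expect_equal(get("spinal_cord", "Dmax"), 45)
  expect_equal(get("esophagus", "Vx", 50), 50)
  expect_equal(get("esophagus", "Dmean"), 34)
  expect_equal(get("esophagus", "Dmax"), 70)
  expect_equal(get("heart", "Vx", 45), 67)
  expect_equal(get("heart", "Vx", 60), 33)

  obj <- imrt_objectives()
  expect_equal(obj$limit[obj$structure == "lung"], 28)
  expect_equal(obj$limit[obj$structure == "spinal_cord"], 40)
})

test_that("constraint checking: OR semantics, inclusive boundaries, margins", {
  # esophagus V50 = 60% but Dmean = 30 Gy -> the OR rule passes
  eso <- dvh_from_points(c(0, 50), c(0.4, 0.6), "esophagus")  # mean 30, V50 60
  plan <- rt_plan("IMRT", 70, list(
    lung = zero_dvh("lung"), esophagus = eso,
    spinal_cord = zero_dvh("spinal_cord"), heart = zero_dvh("heart")))
  res <- check_constraints(plan)
  expect_true(res$pass)
  eso_rows <- res$table[res$table$id == "eso_v50_or_dmean", ]
  expect_equal(eso_rows$atom_pass, c(FALSE, TRUE))  # V50 fails, Dmean saves it
  expect_true(all(eso_rows$rule_pass))

  # all-zero dose passes everything
  plan0 <- rt_plan("IMRT", 70, list(
    lung = zero_dvh("lung"), esophagus = zero_dvh("esophagus"),
    spinal_cord = zero_dvh("spinal_cord"), heart = zero_dvh("heart")))
  expect_true(check_constraints(plan0)$pass)

  # lung V20 exactly 35% passes (inclusive); cord Dmax 45.1 fails by 0.1 Gy
  lung <- dvh_from_points(c(10, 25), c(0.65, 0.35), "lung")
  cord <- dvh_from_points(45.1, 1, "spinal_cord")
  plan2 <- rt_plan("IMRT", 70, list(
    lung = lung, esophagus = zero_dvh("esophagus"),
    spinal_cord = cord, heart = zero_dvh("heart")))
  res2 <- check_constraints(plan2)
  tab <- res2$table
  expect_true(tab$atom_pass[tab$id == "lung_v20"])
  expect_false(res2$pass)
  expect_equal(tab$margin[tab$id == "cord_dmax"], -0.1, tolerance = 1e-9)

  # missing structure is a configuration error
  expect_error(check_constraints(rt_plan("IMRT", 70, list(lung = zero_dvh("lung")))),
               "configuration error")
})

test_that("escalation returns the maximal feasible 2-Gy multiple", {
  # never-violated constraints run to the 110 Gy cap
  p_free <- frac_plan(70)
  expect_equal(as.numeric(escalate_prescription(p_free)), 110)

  # lung V20 (40% of volume at 0.265 x prescription) crosses 35% between
  # 74 and 76 Gy: 20 / 0.265 = 75.47
  p_cross <- frac_plan(70, lung_frac = c(0.05, 0.265), lung_vol = c(0.6, 0.4))
  expect_equal(as.numeric(escalate_prescription(p_cross)), 74)

  # violated already at 58 Gy (crossing at 20/0.351 = 56.9): floored result
  p_low <- frac_plan(70, lung_frac = c(0.05, 0.351), lung_vol = c(0.6, 0.4))
  expect_warning(d_low <- escalate_prescription(p_low), "below")
  expect_equal(as.numeric(d_low), 56)
  expect_true(attr(d_low, "below_floor"))

  # unsatisfiable even at one fraction
  p_bad <- frac_plan(70, lung_frac = 15)  # Dmean = 15 x prescription
  expect_error(escalate_prescription(p_bad), "degenerate")
})

test_that("escalation equals an independent exhaustive sweep", {
  # oracle recomputes every constraint by direct arithmetic on the dose
  # fractions, not via the package's DVH metrics
  oracle_dstar <- function(lung_frac, lung_vol, eso_frac, eso_vol, cord_frac) {
    lung_vol <- lung_vol / sum(lung_vol); eso_vol <- eso_vol / sum(eso_vol)
    feas <- vapply(seq(2, 110, 2), function(D) {
      lv20 <- 100 * sum(lung_vol[lung_frac * D >= 20])
      lmean <- sum(lung_vol * lung_frac) * D
      ev50 <- 100 * sum(eso_vol[eso_frac * D >= 50])
      emean <- sum(eso_vol * eso_frac) * D
      emax <- max(eso_frac) * D
      cmax <- cord_frac * D
      (lv20 <= 35 && lmean <= 20) && cmax <= 45 &&
        ((ev50 <= 50 || emean <= 34) && emax <= 70)
    }, logical(1))
    if (!any(feas)) return(NA_real_)
    max(seq(2, 110, 2)[feas])
  }
  set.seed(13)
  for (i in 1:15) {
    lf <- sort(stats::runif(3, 0.02, 0.45)); lv <- stats::runif(3, 0.1, 1)
    ef <- sort(stats::runif(2, 0.02, 0.9)); ev <- stats::runif(2, 0.1, 1)
    cf <- stats::runif(1, 0.05, 0.5)
    plan <- frac_plan(70, lung_frac = lf, lung_vol = lv,
                      eso_frac = ef, eso_vol = ev, cord_frac = cf)
    expected <- oracle_dstar(lf, lv, ef, ev, cf)
    if (is.na(expected)) {
      expect_error(suppressWarnings(escalate_prescription(plan)), "degenerate")
    } else {
      got <- suppressWarnings(escalate_prescription(plan))
      expect_equal(as.numeric(got), expected)
    }
  }
})

test_that("fraction-matched normalization is exact linear rescaling", {
  dvhs <- list(lung = dvh_from_points(c(5, 20), c(0.7, 0.3), "lung"),
               LN_adj_el = dvh_from_points(c(30, 50), c(0.5, 0.5), "LN_adj_el"))
  imrt <- rt_plan("IMRT", 78, dvhs)
  norm <- normalize_plan(imrt, 72)          # 39 -> 36 fractions, scale 12/13
  expect_equal(norm$technique, "IMRT_norm")
  expect_equal(norm$prescription_dose, 72)
  expect_equal(norm$n_fractions, 36L)
  expect_equal(eud(norm$structures$LN_adj_el, -8),
               (72 / 78) * eud(imrt$structures$LN_adj_el, -8),
               tolerance = 1e-12)

  # identity and round trip
  same <- normalize_plan(imrt, 78)
  expect_equal(same$structures, imrt$structures, tolerance = 1e-15)
  back <- normalize_plan(norm, 78)
  expect_equal(back$structures$LN_adj_el$dose, dvhs$LN_adj_el$dose,
               tolerance = 1e-12)

  expect_error(normalize_plan(imrt, 71), "domain error")
})
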