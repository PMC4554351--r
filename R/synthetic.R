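#' Synthetic cohort generator configuration
#'
#' Parameters of the paired IMRT / 3D-CRT synthetic patient model.  Each
#' patient is a cubic dose grid centred on the carina with a spherical
#' primary tumour in the ipsilateral lung, 13 nodal stations at jittered
#' template positions, and surrogate organs at risk (two lung ellipsoids
#' with the GTV carved out, a spinal-cord cylinder, an esophageal tube and a
#' heart ellipsoid).  The normalized dose is 1 inside the PTV (tumour plus
#' involved stations, each with a 10 mm GTV-to-PTV margin) with a Gaussian
#' falloff of the distance to the PTV surface outside it; the 3D-CRT model
#' additionally lays `n_beams` straight beam corridors through the tumour at
#' `corridor_frac` of the prescription, which is what deposits the extra
#' incidental dose in out-of-field stations.  A small scatter floor keeps
#' far-field doses positive.  Absolute dose is prescription x normalized
#' dose, so every plan scales exactly linearly with its prescription.
#'
#' The defaults encode the study conditions being emulated: 41 patients,
#' 2 Gy fractions, involvement with mean 2.5 stations, and — in the default
#' `"escalate"` prescription mode — falloff/corridor parameters under which
#' constraint-driven escalation lands IMRT prescriptions above 3D-CRT ones,
#' in the low-70s Gy on average.  `"sample"` mode instead draws
#' prescriptions from normal distributions (IMRT 74.3 +/- 9.1 Gy, 3D-CRT
#' 70.1 +/- 7.9 Gy), rounded to the 2 Gy lattice and clamped to
#' \[2, 110\] Gy.
#'
#' @param n_patients cohort size.
#' @param grid_dim grid size in voxels (3 integers).
#' @param spacing voxel spacing in mm.
#' @param gtv_radius_range min/max of the uniform GTV radius draw (mm); the
#'   PTV adds a 10 mm margin (3 mm CTV + 7 mm PTV).
#' @param tumor_offset_mm lateral offset of the tumour centre from midline.
#' @param tumor_jitter_sd per-axis SD of the tumour-centre jitter (mm).
#' @param station_radius nodal station radius (mm).
#' @param station_jitter_sd per-axis SD of station-position jitter (mm).
#' @param sigma_imrt,sigma_3dcrt Gaussian falloff scales (mm); the IMRT
#'   gradient must be steeper (`sigma_imrt < sigma_3dcrt`).
#' @param n_beams number of 3D-CRT beam corridors.
#' @param beam_angles_deg corridor directions in the axial plane (degrees).
#' @param corridor_frac corridor dose as a fraction of prescription.
#' @param corridor_penumbra Gaussian penumbra of the corridor edge (mm).
#' @param imrt_modulation factor in \[0, 1\] applied to the corridor dose of
#'   the IMRT plan: IMRT uses the same beam corridors but modulated down, so
#'   its normalized dose is voxelwise no higher than the 3D-CRT one.  0
#'   removes the IMRT corridors entirely.
#' @param scatter_floor normalized far-field dose floor.
#' @param prescription_mode `"escalate"` (run the 2 Gy escalation loop
#'   against the synthetic OARs; default) or `"sample"` (draw from the
#'   normal distributions below).
#' @param rx_imrt_mean,rx_imrt_sd,rx_3dcrt_mean,rx_3dcrt_sd prescription
#'   distributions for `"sample"` mode (Gy).
#' @param involve_size,involve_p involvement model: the number of involved
#'   stations is `1 + Binomial(involve_size, involve_p)` (defaults give mean
#'   2.5).
#' @param p_right probability the tumour is right-sided.
#' @param bin_width DVH bin width (Gy) at the reference prescription.
#' @param ci_ref_frac fraction of prescription defining the reference
#'   isodose for the conformation number.
#' @param seed master RNG seed (mandatory; all randomness derives from it).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_patients = 41,
                         grid_dim = c(64, 64, 64),
                         spacing = c(4, 4, 4),
                         gtv_radius_range = c(12, 26),
                         tumor_offset_mm = 55,
                         tumor_jitter_sd = 8,
                         station_radius = 12,
                         station_jitter_sd = 3,
                         sigma_imrt = 12,
                         sigma_3dcrt = 20,
                         n_beams = 3,
                         beam_angles_deg = c(0, 120, 240),
                         corridor_frac = 0.30,
                         corridor_penumbra = 6,
                         imrt_modulation = 0.85,
                         scatter_floor = 0.03,
                         prescription_mode = c("escalate", "sample"),
                         rx_imrt_mean = 74.3, rx_imrt_sd = 9.1,
                         rx_3dcrt_mean = 70.1, rx_3dcrt_sd = 7.9,
                         involve_size = 6, involve_p = 0.25,
                         p_right = 0.55,
                         bin_width = 0.1,
                         ci_ref_frac = 0.9) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  prescription_mode <- match.arg(prescription_mode)
  if (sigma_imrt > sigma_3dcrt)
    stop("require sigma_imrt <= sigma_3dcrt (IMRT gradients are steeper)",
         call. = FALSE)
  if (sigma_imrt == sigma_3dcrt)
    warning("sigma_imrt == sigma_3dcrt: techniques are degenerate (falloff identical)",
            call. = FALSE)
  if (length(beam_angles_deg) < n_beams)
    stop("need at least `n_beams` beam angles", call. = FALSE)
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, all(grid_dim > 0),
            length(spacing) == 3L, all(spacing > 0),
            length(gtv_radius_range) == 2L,
            gtv_radius_range[1] > 0, diff(gtv_radius_range) >= 0,
            station_radius > 0, corridor_frac >= 0, corridor_frac < 1,
            scatter_floor >= 0, scatter_floor < 1,
            imrt_modulation >= 0, imrt_modulation <= 1,
            involve_size >= 0, involve_p >= 0, involve_p <= 1,
            n_patients >= 1)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 grid_dim = grid_dim, spacing = as.numeric(spacing),
                 gtv_radius_range = gtv_radius_range,
                 tumor_offset_mm = tumor_offset_mm,
                 tumor_jitter_sd = tumor_jitter_sd,
                 station_radius = station_radius,
                 station_jitter_sd = station_jitter_sd,
                 sigma_imrt = sigma_imrt, sigma_3dcrt = sigma_3dcrt,
                 n_beams = as.integer(n_beams),
                 beam_angles_deg = beam_angles_deg[seq_len(n_beams)],
                 corridor_frac = corridor_frac,
                 corridor_penumbra = corridor_penumbra,
                 imrt_modulation = imrt_modulation,
                 scatter_floor = scatter_floor,
                 prescription_mode = prescription_mode,
                 rx_imrt_mean = rx_imrt_mean, rx_imrt_sd = rx_imrt_sd,
                 rx_3dcrt_mean = rx_3dcrt_mean, rx_3dcrt_sd = rx_3dcrt_sd,
                 involve_size = as.integer(involve_size), involve_p = involve_p,
                 p_right = p_right, bin_width = bin_width,
                 ci_ref_frac = ci_ref_frac),
            class = "synth_config")
}

# Template station centres (mm, carina at the origin; x: +right, y:
# +anterior, z: +cranial). A coarse rendering of a CT-based nodal atlas.
station_template <- function() {
  list("1"      = c(0, 5, 85),
       "2R"     = c(15, 5, 55),
       "2L"     = c(-15, 5, 55),
       "3"      = c(0, 30, 50),
       "4R"     = c(18, 0, 22),
       "4L"     = c(-18, 0, 22),
       "5"      = c(-32, 12, 15),
       "6"      = c(-38, 28, 28),
       "7"      = c(0, -5, -12),
       "8"      = c(0, -18, -45),
       "9"      = c(0, -22, -70),
       "10_11R" = c(45, -5, -15),
       "10_11L" = c(-45, -5, -15))
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

pick1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

#' Draw a nodal involvement set
#'
#' Samples which stations contain macroscopic disease for one patient: the
#' count is `1 + Binomial(involve_size, involve_p)` (every patient has at
#' least one involved station; defaults give mean 2.5), the first station is
#' drawn with weights favouring the ipsilateral lower paratracheal level,
#' the subcarinal station and the ipsilateral hilum, and further stations
#' grow preferentially along the adjacency graph (multilevel spread is
#' anatomically contiguous).  Uses the current RNG state.
#'
#' @param config a [synth_config()].
#' @param tumor_side `"left"` or `"right"`.
#' @param adjacency station adjacency map.
#' @return Character vector of involved station labels.
#' @export
sample_involvement <- function(config, tumor_side,
                               adjacency = default_adjacency()) {
  stopifnot(inherits(config, "synth_config"))
  tumor_side <- match.arg(tumor_side, c("left", "right"))
  vocab <- ln_stations()
  count <- min(1L + stats::rbinom(1L, config$involve_size, config$involve_p),
               length(vocab))
  w <- rep(1, length(vocab))
  names(w) <- vocab
  ipsi <- vocab[station_side(vocab) == tumor_side]
  w[ipsi] <- w[ipsi] + 1
  hot <- c(if (tumor_side == "right") c("4R", "10_11R") else c("4L", "10_11L"), "7")
  w[hot] <- w[hot] + 2
  involved <- pick1(vocab, prob = w)
  while (length(involved) < count) {
    nb <- setdiff(unique(unlist(adjacency[involved], use.names = FALSE)), involved)
    involved <- c(involved,
                  if (length(nb)) pick1(nb) else pick1(setdiff(vocab, involved)))
  }
  involved
}

# squared distance field (array) from voxel centres to a point (mm)
dist2_field <- function(axes, centre) {
  outer(outer((axes[[1]] - centre[1])^2, (axes[[2]] - centre[2])^2, "+"),
        (axes[[3]] - centre[3])^2, "+")
}

ellipsoid_mask <- function(axes, centre, semi) {
  outer(outer(((axes[[1]] - centre[1]) / semi[1])^2,
              ((axes[[2]] - centre[2]) / semi[2])^2, "+"),
        ((axes[[3]] - centre[3]) / semi[3])^2, "+") <= 1
}

# infinite vertical cylinder (tube along z) of radius r at (cx, cy)
tube_mask <- function(axes, cx, cy, r, dims) {
  xy <- outer((axes[[1]] - cx)^2, (axes[[2]] - cy)^2, "+") <= r^2
  array(xy, dim = dims)
}

#' Generate one synthetic patient case
#'
#' Builds the geometry, samples involvement, computes the paired IMRT and
#' 3D-CRT dose distributions, derives DVHs for the PTV, the four OAR
#' surrogates and the two merged elective nodal volumes, and fixes the
#' prescriptions (by constraint-driven escalation or by sampling, per the
#' config).  Deterministic given `patient_seed`.
#'
#' @param config a [synth_config()].
#' @param patient_seed integer seed for this patient's RNG stream.
#' @param id patient identifier.
#' @param keep_geometry keep the dose grids and masks on the returned object
#'   (large; off by default).
#' @return An object of class `patient_case`: `id`, `tumor_side`,
#'   `involved`, `ln_all_el` / `ln_adj_el` station sets, and `plans`, a list
#'   of two [rt_plan()]s (`IMRT`, `3D-CRT`) whose structure DVHs cover
#'   `ptv`, `lung`, `spinal_cord`, `esophagus`, `heart`, `LN_all_el` and
#'   `LN_adj_el`; each plan's `meta` records the conformation number and any
#'   below-60-Gy escalation flag.
#' @export
generate_case <- function(config, patient_seed, id = "p01",
                          keep_geometry = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(patient_seed, {
    dims <- config$grid_dim
    sp <- config$spacing
    extent <- dims * sp
    origin <- -extent / 2
    axes <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 0.5) * sp[k])

    tumor_side <- if (stats::runif(1) < config$p_right) "right" else "left"
    sgn <- if (tumor_side == "right") 1 else -1
    tumor_centre <- c(sgn * config$tumor_offset_mm, 0, 0) +
      stats::rnorm(3, 0, config$tumor_jitter_sd)
    gtv_r <- stats::runif(1, config$gtv_radius_range[1], config$gtv_radius_range[2])
    ptv_r <- gtv_r + 10  # 3 mm CTV + 7 mm PTV margin

    centres <- lapply(station_template(), function(p)
      p + stats::rnorm(3, 0, config$station_jitter_sd))
    r_st <- config$station_radius
    for (s in names(centres)) {
      p <- centres[[s]]
      if (any(p - r_st < origin) || any(p + r_st > origin + extent))
        stop(sprintf("geometry error: station %s placed outside the grid", s),
             call. = FALSE)
    }

    # involvement; redrawn in the (rare) event the adjacent-elective volume
    # would be empty, which would leave nothing to analyse
    repeat {
      involved <- sample_involvement(config, tumor_side)
      case <- nodal_case(involved, tumor_side)
      adj_el <- adjacent_elective(case)
      if (length(adj_el) > 0L) break
    }
    all_el <- all_elective(case)

    # masks ------------------------------------------------------------
    d2_st <- lapply(centres, dist2_field, axes = axes)
    station_masks <- lapply(names(centres), function(s)
      structure_mask(s, d2_st[[s]] <= r_st^2))
    names(station_masks) <- names(centres)

    d2_tumor <- dist2_field(axes, tumor_centre)
    gtv_mask <- d2_tumor <= gtv_r^2

    lung_arr <- (ellipsoid_mask(axes, c(75, 0, 0), c(48, 85, 105)) |
                 ellipsoid_mask(axes, c(-75, 0, 0), c(48, 85, 105))) & !gtv_mask
    oar_masks <- list(
      lung = structure_mask("lung", lung_arr),
      spinal_cord = structure_mask("spinal_cord", tube_mask(axes, 0, -60, 8, dims)),
      esophagus = structure_mask("esophagus", tube_mask(axes, 0, -30, 7, dims)),
      heart = structure_mask("heart",
                             ellipsoid_mask(axes, c(-15, 20, -50), c(50, 40, 40))))

    # PTV: tumour sphere plus involved stations with 7 mm margin --------
    ptv_spheres <- c(list(list(centre = tumor_centre, r = ptv_r)),
                     lapply(involved, function(s)
                       list(centre = centres[[s]], r = r_st + 7)))
    dist_out <- sqrt(d2_tumor) - ptv_r
    ptv_arr <- d2_tumor <= ptv_r^2
    for (s in involved) {
      dist_out <- pmin(dist_out, sqrt(d2_st[[s]]) - (r_st + 7))
      ptv_arr <- ptv_arr | (d2_st[[s]] <= (r_st + 7)^2)
    }
    dist_out <- pmax(dist_out, 0)
    ptv_mask <- structure_mask("ptv", ptv_arr)

    ln_all_mask <- merge_station_volumes(all_el, station_masks, "LN_all_el")
    ln_adj_mask <- merge_station_volumes(adj_el, station_masks, "LN_adj_el")

    # normalized dose fields --------------------------------------------
    norm_dose <- function(sigma, corridor_amp) {
      d <- exp(-dist_out^2 / (2 * sigma^2))
      amp <- config$corridor_frac * corridor_amp
      if (config$n_beams > 0L && amp > 0) {
        for (ang in config$beam_angles_deg) {
          u <- c(cos(ang * pi / 180), sin(ang * pi / 180))
          t2d <- outer(u[1] * (axes[[1]] - tumor_centre[1]),
                       u[2] * (axes[[2]] - tumor_centre[2]), "+")
          t3 <- array(t2d, dim = dims)
          perp <- sqrt(pmax(d2_tumor - t3^2, 0))
          corr <- amp *
            exp(-pmax(perp - ptv_r, 0)^2 / (2 * config$corridor_penumbra^2))
          d <- pmax(d, corr)
        }
      }
      pmax(d, config$scatter_floor)
    }
    fields <- list("IMRT" = norm_dose(config$sigma_imrt,
                                      config$imrt_modulation),
                   "3D-CRT" = norm_dose(config$sigma_3dcrt, 1))

    # plans at a 70 Gy reference, then escalated / sampled ----------------
    ref_rx <- 70
    struct_masks <- c(list(ptv = ptv_mask), oar_masks,
                      list(LN_all_el = ln_all_mask, LN_adj_el = ln_adj_mask))
    plans <- list()
    for (tech in names(fields)) {
      grid <- dose_grid(fields[[tech]] * ref_rx, spacing = sp, origin = origin)
      dvhs <- lapply(struct_masks, function(m)
        compute_dvh(grid, m, bin_width = config$bin_width))
      plan70 <- rt_plan(tech, ref_rx, dvhs, fraction_size = 2)
      rx <- if (config$prescription_mode == "escalate") {
        suppressWarnings(escalate_prescription(plan70))
      } else {
        mu <- if (tech == "IMRT") config$rx_imrt_mean else config$rx_3dcrt_mean
        sd <- if (tech == "IMRT") config$rx_imrt_sd else config$rx_3dcrt_sd
        structure(min(max(2, round(stats::rnorm(1, mu, sd) / 2) * 2), 110),
                  below_floor = FALSE)
      }
      ci <- conformity_index(grid, ptv_mask, config$ci_ref_frac * ref_rx)
      plan <- rt_plan(tech, as.numeric(rx),
                      lapply(dvhs, scale_dvh, s = as.numeric(rx) / ref_rx),
                      fraction_size = 2,
                      meta = list(conformation_number = ci,
                                  below_floor = isTRUE(attr(rx, "below_floor"))))
      if (keep_geometry)
        plan$meta$grid <- dose_grid(fields[[tech]] * as.numeric(rx),
                                    spacing = sp, origin = origin)
      plans[[tech]] <- plan
    }

    out <- list(id = id, patient_seed = patient_seed,
                tumor_side = tumor_side, involved = involved,
                ln_all_el = all_el, ln_adj_el = adj_el,
                gtv_radius = gtv_r, ptv_radius = ptv_r,
                tumor_centre = tumor_centre, station_centres = centres,
                plans = plans)
    if (keep_geometry) out$masks <- c(struct_masks, station_masks)
    structure(out, class = "patient_case")
  })
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: %s-sided, involved {%s}; IMRT %g Gy / 3D-CRT %g Gy\n",
              x$id, x$tumor_side, paste(x$involved, collapse = ", "),
              x$plans[["IMRT"]]$prescription_dose,
              x$plans[["3D-CRT"]]$prescription_dose))
  invisible(x)
}

#' Generate a synthetic paired cohort
#'
#' Draws per-patient seeds from the master seed in `config` (one
#' `sample.int()` draw, documented and stable), then generates each case
#' with [generate_case()].  The same config therefore yields bit-identical
#' cohorts.
#'
#' @param config a [synth_config()].
#' @param keep_geometry passed through to [generate_case()].
#' @return A list of `patient_case` objects of class `ln_cohort`, with the
#'   config attached as attribute `config`.
#' @export
generate_cohort <- function(config, keep_geometry = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_patients
  if (n < 2L)
    warning("cohort of fewer than 2 patients cannot support paired statistics",
            call. = FALSE)
  seeds <- with_local_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, n))
  cases <- lapply(seq_len(n), function(i)
    generate_case(config, seeds[i], id = sprintf("p%02d", i),
                  keep_geometry = keep_geometry))
  structure(cases, class = "ln_cohort", config = config)
}

#' @export
print.ln_cohort <- function(x, ...) {
  rx_i <- vapply(x, function(p) p$plans[["IMRT"]]$prescription_dose, numeric(1))
  rx_c <- vapply(x, function(p) p$plans[["3D-CRT"]]$prescription_dose, numeric(1))
  cat(sprintf("<ln_cohort> %d patients; prescriptions IMRT %.1f +/- %.1f Gy, 3D-CRT %.1f +/- %.1f Gy\n",
              length(x), mean(rx_i), stats::sd(rx_i), mean(rx_c), stats::sd(rx_c)))
  invisible(x)
}
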