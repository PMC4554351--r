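#' Dose-volume histograms
#'
#' A DVH summarises the distribution of absorbed dose over a structure.  The
#' differential form stores the fraction of the structure volume `volume[i]`
#' receiving dose `dose[i]`; the cumulative form stores, at each tabulated
#' dose, the fraction of the volume receiving at least that dose.  Both forms
#' share the same dose coordinates, so they interconvert losslessly.
#'
#' Differential DVHs always carry a leading anchor at 0 Gy (possibly with zero
#' mass); cumulative DVHs therefore always start at (0 Gy, 1).  Histograms
#' derived from a dose grid by [compute_dvh()] use bin midpoints as dose
#' coordinates and record the bin width; DVHs built from exact dose points by
#' [dvh_from_points()] have no bin width and their metrics are exact.
#'
#' @name dvh
#' @keywords internal
NULL

new_dvh <- function(structure, form, dose, volume, total_volume_cc = NA_real_,
                    bin_width = NA_real_) {
  x <- structure(list(structure = structure, form = form,
                      dose = as.numeric(dose), volume = as.numeric(volume),
                      total_volume_cc = as.numeric(total_volume_cc),
                      bin_width = as.numeric(bin_width)),
                 class = "dvh")
  validate_dvh(x)
  x
}

validate_dvh <- function(x) {
  if (!inherits(x, "dvh")) stop("not a dvh object", call. = FALSE)
  if (!x$form %in% c("differential", "cumulative"))
    stop("dvh form must be 'differential' or 'cumulative'", call. = FALSE)
  d <- x$dose; v <- x$volume
  if (length(d) == 0L || length(d) != length(v))
    stop("dvh dose and volume vectors must be non-empty and equal length",
         call. = FALSE)
  if (anyNA(d) || anyNA(v) || any(!is.finite(d)) || any(!is.finite(v)))
    stop("dvh values must be finite", call. = FALSE)
  if (any(diff(d) <= 0) || d[1] < 0)
    stop("dvh dose coordinates must be non-negative and strictly increasing",
         call. = FALSE)
  if (x$form == "differential") {
    if (d[1] != 0)
      stop("differential dvh must start with a 0 Gy anchor", call. = FALSE)
    if (any(v < -1e-12))
      stop("differential volumes must be non-negative", call. = FALSE)
    if (abs(sum(v) - 1) > 1e-9)
      stop("differential volumes must sum to 1 (±1e-9)", call. = FALSE)
  } else {
    if (d[1] != 0 || abs(v[1] - 1) > 1e-9)
      stop("cumulative dvh must have value 1 at dose 0", call. = FALSE)
    if (any(diff(v) > 1e-12))
      stop("cumulative dvh must be monotone non-increasing", call. = FALSE)
    if (any(v < -1e-12) || any(v > 1 + 1e-9))
      stop("cumulative volumes must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Build a DVH from exact dose points
#'
#' Constructs a differential DVH that places the given relative volumes at the
#' given doses exactly (no binning).  Volumes are normalised to sum to 1, so
#' raw voxel counts may be supplied.  Duplicate doses are aggregated.
#'
#' @param doses numeric vector of doses (Gy), non-negative.
#' @param volumes relative volumes (or counts) at each dose; default equal
#'   weights.
#' @param structure structure label.
#' @param total_volume_cc optional absolute volume (cc).
#' @return A differential `dvh`.
#' @examples
#' dvh_from_points(c(20, 60), c(0.25, 0.75))
#' @export
dvh_from_points <- function(doses, volumes = NULL, structure = "structure",
                            total_volume_cc = NA_real_) {
  doses <- as.numeric(doses)
  if (length(doses) == 0L) stop("structure-empty error: no dose points", call. = FALSE)
  if (anyNA(doses) || any(!is.finite(doses)) || any(doses < 0))
    stop("doses must be finite and non-negative", call. = FALSE)
  if (is.null(volumes)) volumes <- rep(1, length(doses))
  volumes <- as.numeric(volumes)
  if (length(volumes) != length(doses) || any(volumes < 0) || sum(volumes) <= 0)
    stop("volumes must be non-negative with positive total", call. = FALSE)
  v <- tapply(volumes, doses, sum)
  d <- as.numeric(names(v))
  o <- order(d)
  d <- d[o]; v <- as.numeric(v)[o] / sum(v)
  if (d[1] > 0) { d <- c(0, d); v <- c(0, v) }
  new_dvh(structure, "differential", d, v, total_volume_cc)
}

#' Compute a DVH from a dose grid and structure mask
#'
#' Histograms the masked voxel doses into left-closed, right-open bins
#' `[k*w, (k+1)*w)` of width `w = bin_width`, covering `[0, max dose in
#' mask]` (the top bin is the one containing the maximum dose).  Each voxel
#' contributes weight 1/N.  Dose coordinates of the returned differential DVH
#' are bin midpoints (plus a zero-mass 0 Gy anchor), so histogram-based
#' metrics carry a quantisation error of at most half a bin.
#'
#' @param grid a [dose_grid()].
#' @param mask a [structure_mask()] congruent with `grid` and non-empty.
#' @param bin_width bin width in Gy (> 0); default 0.1.
#' @return A differential `dvh` carrying `total_volume_cc` and `bin_width`.
#' @export
compute_dvh <- function(grid, mask, bin_width = 0.1) {
  stopifnot(is_dose_grid(grid), is_structure_mask(mask))
  check_congruent(grid, mask)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number", call. = FALSE)
  doses <- grid$values[mask$mask]
  n <- length(doses)
  if (n == 0L)
    stop(sprintf("structure-empty error: mask '%s' has no voxels", mask$name),
         call. = FALSE)
  dmax <- max(doses)
  nbin <- as.integer(floor(dmax / bin_width)) + 1L
  idx <- pmin(floor(doses / bin_width), nbin - 1L) + 1L
  counts <- tabulate(idx, nbins = nbin)
  mid <- (seq_len(nbin) - 0.5) * bin_width
  new_dvh(mask$name, "differential",
          dose = c(0, mid), volume = c(0, counts / n),
          total_volume_cc = n * voxel_volume_cc(grid),
          bin_width = bin_width)
}

#' Convert between differential and cumulative DVH forms
#'
#' The two forms share dose coordinates, so the round trip
#' `to_differential(to_cumulative(x))` reproduces `x` exactly.  A cumulative
#' DVH tabulates, at each dose coordinate, the volume fraction receiving at
#' least that dose (value 1 at 0 Gy).
#'
#' @param dvh a `dvh` object.
#' @return A `dvh` of the requested form (input returned unchanged when it is
#'   already in that form).
#' @export
to_cumulative <- function(dvh) {
  validate_dvh(dvh)
  if (dvh$form == "cumulative") return(dvh)
  v <- rev(cumsum(rev(dvh$volume)))
  v[1] <- 1  # absorb rounding in the sum-to-1 invariant
  new_dvh(dvh$structure, "cumulative", dvh$dose, v,
          dvh$total_volume_cc, dvh$bin_width)
}

#' @rdname to_cumulative
#' @export
to_differential <- function(dvh) {
  validate_dvh(dvh)
  if (dvh$form == "differential") return(dvh)
  v <- c(-diff(dvh$volume), dvh$volume[length(dvh$volume)])
  v[v < 0 & v > -1e-12] <- 0
  new_dvh(dvh$structure, "differential", dvh$dose, v,
          dvh$total_volume_cc, dvh$bin_width)
}

#' Rescale the dose axis of a DVH
#'
#' Multiplies every dose coordinate (and the bin width, if any) by `s`,
#' leaving volumes untouched — the DVH of the same structure under a linearly
#' rescaled plan.
#'
#' @param dvh a `dvh` object.
#' @param s positive scale factor.
#' @return The rescaled `dvh`.
#' @export
scale_dvh <- function(dvh, s) {
  validate_dvh(dvh)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("`s` must be a single positive number", call. = FALSE)
  new_dvh(dvh$structure, dvh$form, dvh$dose * s, dvh$volume,
          dvh$total_volume_cc, dvh$bin_width * s)
}

#' @export
print.dvh <- function(x, ...) {
  occ <- if (x$form == "differential") sum(x$volume > 0) else length(x$volume)
  cat(sprintf("<dvh> '%s' (%s): %d dose points, mean %.2f Gy%s\n",
              x$structure, x$form, occ, metric_mean(x),
              if (is.na(x$total_volume_cc)) ""
              else sprintf(", %.1f cc", x$total_volume_cc)))
  invisible(x)
}

# ---- scalar metrics ---------------------------------------------------------

#' DVH plan-quality metrics
#'
#' Scalar metrics evaluated on a DVH (either form):
#' * `metric_mean()` — mean dose, \eqn{\sum_i v_i d_i} over the differential
#'   form (bin midpoints for histogram DVHs).
#' * `metric_max()` — maximum dose; for histogram DVHs the upper edge of the
#'   highest occupied bin, otherwise the highest occupied dose point.
#' * `metric_Dx()` — minimum dose received by the hottest `x`% of the volume,
#'   i.e. the largest dose received by at least `x`% (0 < x <= 100).
#' * `metric_Vx()` — percentage of the volume receiving at least `x` Gy.
#'
#' `metric_Dx()` and `metric_Vx()` read the cumulative curve.  The default
#' `interp = "step"` treats the DVH as the discrete distribution it tabulates
#' (exact for point DVHs); `interp = "linear"` interpolates linearly between
#' tabulated cumulative points.
#'
#' @param dvh a `dvh` object.
#' @param x percentage of volume (`metric_Dx`) or dose in Gy (`metric_Vx`).
#' @param interp `"step"` or `"linear"` evaluation of the cumulative curve.
#' @return Dose in Gy (`metric_mean`, `metric_max`, `metric_Dx`) or percent
#'   volume in \[0, 100\] (`metric_Vx`).
#' @examples
#' d <- dvh_from_points(c(20, 60), c(0.25, 0.75))
#' metric_mean(d)      # 50 Gy
#' metric_Dx(d, 90)    # 20 Gy
#' metric_Vx(d, 35)    # 75 %
#' @export
metric_mean <- function(dvh) {
  dd <- to_differential(dvh)
  sum(dd$volume * dd$dose)
}

#' @rdname metric_mean
#' @export
metric_max <- function(dvh) {
  dd <- to_differential(dvh)
  occ <- dd$volume > 0
  if (!any(occ)) return(0)
  top <- max(dd$dose[occ])
  if (!is.na(dd$bin_width) && top > 0) top + dd$bin_width / 2 else top
}

#' @rdname metric_mean
#' @export
metric_Vx <- function(dvh, x, interp = c("step", "linear")) {
  interp <- match.arg(interp)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("domain error: `x` must be a single dose >= 0 Gy", call. = FALSE)
  dd <- to_differential(dvh)
  if (interp == "step")
    return(100 * sum(dd$volume[dd$dose >= x - 1e-12]))
  cc <- to_cumulative(dvh)
  if (x <= cc$dose[1]) return(100)
  n <- length(cc$dose)
  if (x >= cc$dose[n]) {
    if (x > cc$dose[n] + 1e-12) return(0)
    return(100 * cc$volume[n])
  }
  100 * stats::approx(cc$dose, cc$volume, xout = x, method = "linear")$y
}

#' @rdname metric_mean
#' @export
metric_Dx <- function(dvh, x, interp = c("step", "linear")) {
  interp <- match.arg(interp)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x > 100)
    stop("domain error: `x` must be a volume percentage in (0, 100]", call. = FALSE)
  cc <- to_cumulative(dvh)
  p <- x / 100
  ok <- cc$volume >= p - 1e-12
  if (interp == "step") return(max(cc$dose[ok]))
  # linear: invert the piecewise-linear cumulative curve
  i <- max(which(ok))
  if (i == length(cc$dose)) return(cc$dose[i])
  v1 <- cc$volume[i]; v2 <- cc$volume[i + 1]
  if (v2 >= p - 1e-12 || v1 - v2 < 1e-15) return(cc$dose[i + 1])
  cc$dose[i] + (v1 - p) / (v1 - v2) * (cc$dose[i + 1] - cc$dose[i])
}

# ---- conformity -------------------------------------------------------------

#' Conformity of a reference isodose to the PTV
#'
#' `conformity_index()` returns the van't Riet / Paddick conformation number
#' \deqn{CN = \frac{TV_{PIV}^2}{TV \cdot PIV},}
#' where `TV` is the PTV volume, `PIV` the volume receiving at least
#' `reference_dose`, and `TV_PIV` their intersection.  CN lies in \[0, 1\]
#' and equals 1 exactly when the reference isodose volume coincides with the
#' PTV.  `conformity_ratio_rtog()` returns the simpler RTOG ratio `PIV / TV`
#' (1 is ideal, > 1 means spill) for comparison.
#'
#' @param grid a [dose_grid()].
#' @param ptv a non-empty [structure_mask()] congruent with `grid`.
#' @param reference_dose reference isodose level in Gy (> 0); voxels with dose
#'   >= this level form the PIV.
#' @return A dimensionless scalar.
#' @export
conformity_index <- function(grid, ptv, reference_dose) {
  stopifnot(is_dose_grid(grid), is_structure_mask(ptv))
  check_congruent(grid, ptv)
  if (!is.numeric(reference_dose) || length(reference_dose) != 1L || reference_dose <= 0)
    stop("`reference_dose` must be a single positive dose (Gy)", call. = FALSE)
  tv <- sum(ptv$mask)
  if (tv == 0L)
    stop(sprintf("structure-empty error: PTV '%s' has no voxels", ptv$name),
         call. = FALSE)
  piv_mask <- grid$values >= reference_dose
  piv <- sum(piv_mask)
  if (piv == 0L) return(0)
  tv_piv <- sum(piv_mask & ptv$mask)
  (tv_piv^2) / (tv * piv)
}

#' @rdname conformity_index
#' @export
conformity_ratio_rtog <- function(grid, ptv, reference_dose) {
  stopifnot(is_dose_grid(grid), is_structure_mask(ptv))
  check_congruent(grid, ptv)
  if (!is.numeric(reference_dose) || length(reference_dose) != 1L || reference_dose <= 0)
    stop("`reference_dose` must be a single positive dose (Gy)", call. = FALSE)
  tv <- sum(ptv$mask)
  if (tv == 0L)
    stop(sprintf("structure-empty error: PTV '%s' has no voxels", ptv$name),
         call. = FALSE)
  sum(grid$values >= reference_dose) / tv
}
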