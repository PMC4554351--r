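#' Treatment plan
#'
#' A plan bundles the delivery technique, prescription, fractionation and the
#' per-structure dose summaries (DVHs) it produced.  The prescription must be
#' an exact multiple of the fraction size (2 Gy fractions by default) and may
#' not exceed the 110 Gy cap.  All plan-level operations in this package
#' ([normalize_plan()], [escalate_prescription()]) exploit the fact that the
#' dose distribution scales linearly with the prescription.
#'
#' @param technique `"IMRT"`, `"3D-CRT"` or `"IMRT_norm"`.
#' @param prescription_dose total prescription dose in Gy.
#' @param structures named list of `dvh` objects, one per structure.
#' @param fraction_size dose per fraction in Gy (default 2).
#' @param meta optional list of extra per-plan metadata (e.g. a conformity
#'   index computed at generation time).
#' @return An object of class `rt_plan` with an `n_fractions` element.
#' @export
rt_plan <- function(technique, prescription_dose, structures = list(),
                    fraction_size = 2, meta = list()) {
  technique <- match.arg(technique, c("IMRT", "3D-CRT", "IMRT_norm"))
  if (!is.numeric(prescription_dose) || length(prescription_dose) != 1L ||
      !is.finite(prescription_dose) || prescription_dose <= 0)
    stop("`prescription_dose` must be a single positive dose (Gy)", call. = FALSE)
  if (prescription_dose > 110 + 1e-9)
    stop("prescription exceeds the 110 Gy cap", call. = FALSE)
  nf <- prescription_dose / fraction_size
  if (abs(nf - round(nf)) > 1e-9)
    stop("`prescription_dose` must be an exact multiple of `fraction_size`",
         call. = FALSE)
  if (length(structures)) {
    if (is.null(names(structures)) || any(!nzchar(names(structures))))
      stop("`structures` must be a named list of dvh objects", call. = FALSE)
    lapply(structures, validate_dvh)
  }
  structure(list(technique = technique,
                 prescription_dose = prescription_dose,
                 fraction_size = fraction_size,
                 n_fractions = as.integer(round(nf)),
                 structures = structures,
                 meta = meta),
            class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan> %s: %g Gy in %d x %g Gy fractions; %d structure DVH(s)\n",
              x$technique, x$prescription_dose, x$n_fractions,
              x$fraction_size, length(x$structures)))
  invisible(x)
}

# Linear rescale of every structure DVH plus the prescription. Internal: the
# scaled prescription need not sit on the fraction lattice mid-search.
scale_plan <- function(plan, s) {
  stopifnot(inherits(plan, "rt_plan"))
  out <- plan
  out$prescription_dose <- plan$prescription_dose * s
  out$structures <- lapply(plan$structures, scale_dvh, s = s)
  out
}

#' Organ-at-risk constraint sets
#'
#' `default_constraints()` returns the normal-tissue limits used as the hard
#' gate for prescription escalation: whole lung (GTV subtracted) V20 <= 35%
#' and mean dose <= 20 Gy; spinal cord Dmax <= 45 Gy; esophagus (V50 <= 50%
#' OR mean dose <= 34 Gy) and Dmax <= 70 Gy; heart V45 <= 67% and V60 <= 33%.
#' That is 7 constraint rules across 4 organs; the esophagus OR-pair is one
#' rule with two alternative atoms (rows sharing an `id` pass if either atom
#' passes).
#'
#' `imrt_objectives()` returns the tighter starting objectives used when
#' inverse-optimising an initial IMRT plan (lung V20 < 28%, heart V40 < 20%,
#' cord Dmax 40 Gy, esophagus V50 < 50% and Dmax 70 Gy).  They are planning
#' objectives, not a feasibility gate, but can be used by the synthetic
#' generator to differentiate techniques.
#'
#' @return A data frame of class `constraint_set` with columns `id`,
#'   `structure`, `metric` (`"Vx"`, `"Dmean"` or `"Dmax"`), `x` (the dose
#'   threshold of a Vx metric, Gy; NA otherwise) and `limit` (% for Vx, Gy
#'   for dose metrics).
#' @examples
#' default_constraints()
#' @export
default_constraints <- function() {
  cs <- data.frame(
    id = c("lung_v20", "lung_dmean", "cord_dmax",
           "eso_v50_or_dmean", "eso_v50_or_dmean", "eso_dmax",
           "heart_v45", "heart_v60"),
    structure = c("lung", "lung", "spinal_cord",
                  "esophagus", "esophagus", "esophagus",
                  "heart", "heart"),
    metric = c("Vx", "Dmean", "Dmax", "Vx", "Dmean", "Dmax", "Vx", "Vx"),
    x = c(20, NA, NA, 50, NA, NA, 45, 60),
    limit = c(35, 20, 45, 50, 34, 70, 67, 33),
    stringsAsFactors = FALSE)
  class(cs) <- c("constraint_set", "data.frame")
  cs
}

#' @rdname default_constraints
#' @export
imrt_objectives <- function() {
  cs <- data.frame(
    id = c("lung_v20", "heart_v40", "cord_dmax", "eso_v50", "eso_dmax"),
    structure = c("lung", "heart", "spinal_cord", "esophagus", "esophagus"),
    metric = c("Vx", "Vx", "Dmax", "Vx", "Dmax"),
    x = c(20, 40, NA, 50, NA),
    limit = c(28, 20, 40, 50, 70),
    stringsAsFactors = FALSE)
  class(cs) <- c("constraint_set", "data.frame")
  cs
}

validate_constraint_set <- function(cs) {
  req <- c("id", "structure", "metric", "x", "limit")
  if (!is.data.frame(cs) || !all(req %in% names(cs)))
    stop("a constraint set needs columns id, structure, metric, x, limit",
         call. = FALSE)
  if (any(!cs$metric %in% c("Vx", "Dmean", "Dmax")))
    stop("constraint metric must be one of Vx, Dmean, Dmax", call. = FALSE)
  if (any(!is.finite(cs$limit)) || any(cs$limit <= 0))
    stop("constraint limits must be positive", call. = FALSE)
  if (any(cs$metric == "Vx" & !is.finite(cs$x)))
    stop("Vx constraints need a dose threshold `x`", call. = FALSE)
  invisible(cs)
}

#' Evaluate a plan against a constraint set
#'
#' Computes each constrained metric from the plan's structure DVHs and
#' compares it (inclusively, `<=`) with its limit.  Rows sharing an `id` are
#' alternatives: the rule passes if any of its atoms passes.  The plan passes
#' when every rule passes.
#'
#' @param plan an [rt_plan()] whose `structures` include every constrained
#'   structure.
#' @param constraints a constraint set, e.g. [default_constraints()].
#' @return A list with `pass` (logical) and `table`, a data frame with one
#'   row per atom: achieved `value`, `margin` (limit - value; positive means
#'   headroom, in % for Vx rows and Gy otherwise), `atom_pass` and
#'   `rule_pass`.
#' @export
check_constraints <- function(plan, constraints = default_constraints()) {
  stopifnot(inherits(plan, "rt_plan"))
  validate_constraint_set(constraints)
  missing <- setdiff(unique(constraints$structure), names(plan$structures))
  if (length(missing))
    stop(sprintf("configuration error: plan lacks DVHs for constrained structure(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  value <- vapply(seq_len(nrow(constraints)), function(i) {
    dvh <- plan$structures[[constraints$structure[i]]]
    switch(constraints$metric[i],
           Vx = metric_Vx(dvh, constraints$x[i]),
           Dmean = metric_mean(dvh),
           Dmax = metric_max(dvh))
  }, numeric(1))
  tab <- constraints
  tab$value <- value
  tab$margin <- tab$limit - value
  tab$atom_pass <- value <= tab$limit + 1e-9
  rule_pass <- tapply(tab$atom_pass, tab$id, any)
  tab$rule_pass <- as.logical(rule_pass[tab$id])
  rownames(tab) <- NULL
  class(tab) <- "data.frame"
  list(pass = all(rule_pass), table = tab)
}

#' Constraint-driven prescription escalation
#'
#' Finds the prescription the plan can carry: the dose distribution is
#' assumed to scale linearly with the prescription, and the feasibility of
#' every multiple of `step` in `[step, cap]` is evaluated by rescaling the
#' plan and checking `constraints`.  The maximal feasible multiple is
#' returned (the exhaustive sweep, rather than a walk from `start`,
#' guarantees the argmax even if a synthetic constraint curve is
#' non-monotone; a warning is emitted when the feasible set is not a prefix
#' of the lattice).  De-escalation below `start` happens naturally; a result
#' below `floor` (the 60 Gy aspiration) is flagged via the `below_floor`
#' attribute and a warning.
#'
#' @param plan an [rt_plan()] with DVHs for all constrained structures.
#' @param constraints constraint set; [default_constraints()] by default.
#' @param start nominal starting prescription (Gy); informational.
#' @param step escalation step (Gy), default 2.
#' @param cap maximum allowed prescription (Gy), default 110.
#' @param floor aspired minimal prescription (Gy), default 60.
#' @return The maximal feasible prescription (Gy) with attribute
#'   `below_floor`.  Errors if no lattice dose is feasible.
#' @export
escalate_prescription <- function(plan, constraints = default_constraints(),
                                  start = 70, step = 2, cap = 110, floor = 60) {
  stopifnot(inherits(plan, "rt_plan"))
  if (step <= 0 || cap < step)
    stop("need step > 0 and cap >= step", call. = FALSE)
  candidates <- seq(step, cap, by = step)
  p0 <- plan$prescription_dose
  feasible <- vapply(candidates, function(D) {
    check_constraints(scale_plan(plan, D / p0), constraints)$pass
  }, logical(1))
  if (!any(feasible))
    stop("degenerate case: constraints unsatisfiable at every lattice dose",
         call. = FALSE)
  d_star <- max(candidates[feasible])
  if (any(!feasible[candidates < d_star]))
    warning("constraint feasibility is non-monotone in prescription dose",
            call. = FALSE)
  below <- d_star < floor
  if (below)
    warning(sprintf("maximal feasible prescription %g Gy is below the %g Gy aspiration",
                    d_star, floor), call. = FALSE)
  structure(d_star, below_floor = below)
}

#' Fraction-matched plan normalization
#'
#' Rescales a plan to a different total prescription by matching fraction
#' counts at a fixed fraction size — with identical 2 Gy fractions this is a
#' pure linear scaling of every dose in the plan, so EUD, mean dose and Dmax
#' all scale by exactly `target_prescription / prescription_dose`.  An IMRT
#' plan normalized this way is relabelled `IMRT_norm` (the convention for an
#' IMRT plan rescaled to its paired 3D-CRT reference dose).  Note this is
#' fraction matching of the whole distribution, not a point-dose match.
#'
#' @param plan an [rt_plan()].
#' @param target_prescription target total dose (Gy); must be a multiple of
#'   the plan's fraction size.
#' @return A new [rt_plan()] at the target prescription.
#' @export
normalize_plan <- function(plan, target_prescription) {
  stopifnot(inherits(plan, "rt_plan"))
  if (!is.numeric(target_prescription) || length(target_prescription) != 1L ||
      !is.finite(target_prescription) || target_prescription <= 0)
    stop("`target_prescription` must be a single positive dose (Gy)", call. = FALSE)
  nf <- target_prescription / plan$fraction_size
  if (abs(nf - round(nf)) > 1e-9)
    stop("domain error: target prescription is not a multiple of the fraction size",
         call. = FALSE)
  s <- target_prescription / plan$prescription_dose
  out <- scale_plan(plan, s)
  out$n_fractions <- as.integer(round(nf))
  if (plan$technique == "IMRT") out$technique <- "IMRT_norm"
  out
}
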