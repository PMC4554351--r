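#' Dose grid
#'
#' A 3D lattice of absorbed dose together with its voxel spacing and the
#' physical coordinate of the corner of voxel (1,1,1). Doses are in Gy,
#' geometry in mm. Voxel volumes are uniform (the product of the spacings);
#' masks are binary, so partial-volume effects at structure boundaries are
#' ignored.
#'
#' @param values 3D numeric array of absorbed dose (Gy); all values must be
#'   finite and non-negative.
#' @param spacing numeric vector of 3 positive voxel edge lengths (mm).
#' @param origin physical coordinate (mm) of the corner of the first voxel.
#' @return An object of class `dose_grid` with elements `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- dose_grid(array(10, c(4, 4, 4)), spacing = c(2, 2, 2))
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (length(values) == 0L)
    stop("dose lattice is empty", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("dose values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("dose values must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive lengths (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite coordinates (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' Structure mask
#'
#' Boolean lattice congruent with an associated [dose_grid()], marking the
#' voxels belonging to one anatomic region of interest.
#'
#' @param name structure label.
#' @param mask 3D logical array, same shape as the associated dose grid.
#' @return An object of class `structure_mask` with elements `name`, `mask`.
#' @export
structure_mask <- function(name, mask) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a single non-empty string", call. = FALSE)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  if (!is.logical(mask) || anyNA(mask))
    stop("`mask` must be logical with no missing values", call. = FALSE)
  structure(list(name = name, mask = mask), class = "structure_mask")
}

is_dose_grid <- function(x) inherits(x, "dose_grid")
is_structure_mask <- function(x) inherits(x, "structure_mask")

check_congruent <- function(grid, mask) {
  if (!identical(dim(grid$values), dim(mask$mask)))
    stop(sprintf("geometry error: mask '%s' (%s) is not congruent with grid (%s)",
                 mask$name, paste(dim(mask$mask), collapse = "x"),
                 paste(dim(grid$values), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels @ %s mm, dose %.2f-%.2f Gy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d of %d voxels\n",
              x$name, sum(x$mask), length(x$mask)))
  invisible(x)
}

# Physical voxel-centre coordinates along each axis (mm).
grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(k) grid$origin[k] + (seq_len(d[k]) - 0.5) * grid$spacing[k])
}

# Voxel volume in cc.
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000
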