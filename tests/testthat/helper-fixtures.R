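# shared fixtures: everything is generated in code, nothing on disk

make_uniform_grid <- function(dose, dims = c(5, 5, 5), spacing = c(2, 2, 2)) {
  dose_grid(array(dose, dims), spacing = spacing)
}

full_mask <- function(grid, name = "roi") {
  structure_mask(name, array(TRUE, dim(grid$values)))
}

rand_grid <- function(dims = c(8, 8, 8), lo = 0.5, hi = 70) {
  dose_grid(array(stats::runif(prod(dims), lo, hi), dims), spacing = c(2, 2, 2))
}

rand_point_dvh <- function(k = 8, lo = 0.5, hi = 70) {
  dvh_from_points(stats::runif(k, lo, hi), stats::runif(k, 0.1, 1))
}

# an all-zero-dose DVH (passes every OAR constraint)
zero_dvh <- function(name = "s") dvh_from_points(0, 1, structure = name)

# plan whose OAR doses are simple known multiples of the prescription,
# handy for escalation tests: each structure gets point doses
# prescription * frac with the given relative volumes
frac_plan <- function(prescription, technique = "IMRT",
                      lung_frac = c(0.05), lung_vol = c(1),
                      eso_frac = c(0.05), eso_vol = c(1),
                      cord_frac = 0.05, heart_frac = c(0.05),
                      heart_vol = c(1)) {
  rt_plan(technique, prescription, list(
    lung = dvh_from_points(prescription * lung_frac, lung_vol, "lung"),
    esophagus = dvh_from_points(prescription * eso_frac, eso_vol, "esophagus"),
    spinal_cord = dvh_from_points(prescription * cord_frac, 1, "spinal_cord"),
    heart = dvh_from_points(prescription * heart_frac, heart_vol, "heart")))
}

# small, fast generator configuration (same 256 mm extent, coarser voxels)
tiny_config <- function(seed, n = 3, ...) {
  synth_config(seed = seed, n_patients = n, grid_dim = c(32, 32, 32),
               spacing = c(8, 8, 8), ...)
}
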