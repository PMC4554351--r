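#' Read and write dose grids
#'
#' On-disk format: raw little-endian float32 dose values (column-major, Gy)
#' in `<prefix>.raw` plus a JSON sidecar `<prefix>.json` with fields
#' `shape`, `spacing_mm` and `origin_mm`.
#'
#' @param grid a [dose_grid()].
#' @param prefix path prefix (without extension).
#' @return `read_dose_grid()` returns a [dose_grid()];
#'   `write_dose_grid()` returns `prefix` invisibly.
#' @export
write_dose_grid <- function(grid, prefix) {
  stopifnot(is_dose_grid(grid))
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid$values), con, size = 4L, endian = "little")
  jsonlite::write_json(list(shape = dim(grid$values),
                            spacing_mm = grid$spacing,
                            origin_mm = grid$origin),
                       paste0(prefix, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(prefix)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L) stop("sidecar `shape` must have 3 entries", call. = FALSE)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(shape), size = 4L, endian = "little")
  if (length(vals) != prod(shape))
    stop("raw dose file shorter than the sidecar shape implies", call. = FALSE)
  # float32 round-off can leave tiny negatives on zero doses
  vals[vals < 0 & vals > -1e-6] <- 0
  dose_grid(array(vals, dim = shape), spacing = meta$spacing_mm,
            origin = meta$origin_mm)
}

#' Read and write structure masks
#'
#' On-disk format: JSON run-length encoding over the column-major linear
#' index (0-based starts), with fields `name`, `shape`, `starts`, `lengths`.
#'
#' @param mask a [structure_mask()].
#' @param path JSON file path.
#' @return `read_structure_mask()` returns a [structure_mask()].
#' @export
write_structure_mask <- function(mask, path) {
  stopifnot(is_structure_mask(mask))
  v <- as.vector(mask$mask)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values
  jsonlite::write_json(list(name = mask$name, shape = dim(mask$mask),
                            starts = starts[keep], lengths = r$lengths[keep]),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_structure_mask
#' @export
read_structure_mask <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  m <- logical(prod(shape))
  starts <- as.integer(meta$starts)
  lens <- as.integer(meta$lengths)
  if (length(starts) != length(lens))
    stop("mask RLE starts/lengths mismatch", call. = FALSE)
  for (i in seq_along(starts))
    m[(starts[i] + 1L):(starts[i] + lens[i])] <- TRUE
  structure_mask(as.character(meta$name), array(m, dim = shape))
}

#' Read and write DVHs as CSV
#'
#' Format: a two-line metadata header (`structure,form,total_volume_cc` and
#' its values) followed by a `dose_gy,volume_rel` table.  The reader
#' re-validates all DVH invariants.
#'
#' @param dvh a `dvh` object.
#' @param path CSV file path.
#' @return `read_dvh_csv()` returns a validated `dvh`.
#' @export
write_dvh_csv <- function(dvh, path) {
  validate_dvh(dvh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("structure,form,total_volume_cc", con)
  writeLines(sprintf("%s,%s,%s", dvh$structure, dvh$form,
                     ifelse(is.na(dvh$total_volume_cc), "NA",
                            format(dvh$total_volume_cc, digits = 17))), con)
  writeLines("dose_gy,volume_rel", con)
  writeLines(sprintf("%s,%s", format(dvh$dose, digits = 17, trim = TRUE),
                     format(dvh$volume, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @export
read_dvh_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || lines[1] != "structure,form,total_volume_cc" ||
      lines[3] != "dose_gy,volume_rel")
    stop("not a DVH CSV file: ", path, call. = FALSE)
  meta <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  tab <- utils::read.csv(text = lines[-(1:2)])
  new_dvh(meta[1], meta[2], tab$dose_gy, tab$volume_rel,
          total_volume_cc = suppressWarnings(as.numeric(meta[3])))
}

#' Read a station adjacency map from JSON
#'
#' The file holds an edge list: a JSON array of two-element station-label
#' arrays.  The resulting symmetric graph must cover the whole
#' [ln_stations()] vocabulary (stations without edges simply get no
#' neighbours).
#'
#' @param path JSON file path.
#' @return Named adjacency list as from [default_adjacency()].
#' @export
read_adjacency_json <- function(path) {
  edges <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.matrix(edges)) edges <- split(edges, row(edges))
  adjacency_from_edges(lapply(edges, as.character))
}

#' Write or read a simulated cohort directory
#'
#' `write_cohort()` lays a cohort out as one sub-directory per patient with
#' a `meta.json` (id, seed, side, involvement, grouped station sets and
#' per-plan prescription/meta) and one DVH CSV per structure and plan
#' (`<technique>_<structure>.csv`, technique with `3D-CRT` spelled
#' `3DCRT`).  `read_cohort()` reconstructs the `patient_case` objects
#' (DVH-based; grids and masks are not stored).
#'
#' @param cohort an `ln_cohort` from [generate_cohort()].
#' @param dir target directory (created if needed).
#' @return `read_cohort()` returns an `ln_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ln_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort) {
    pdir <- file.path(dir, case$id)
    dir.create(pdir, showWarnings = FALSE)
    meta <- list(id = case$id, patient_seed = case$patient_seed,
                 tumor_side = case$tumor_side, involved = case$involved,
                 ln_all_el = case$ln_all_el, ln_adj_el = case$ln_adj_el,
                 gtv_radius = case$gtv_radius, ptv_radius = case$ptv_radius,
                 plans = lapply(case$plans, function(p)
                   list(technique = p$technique,
                        prescription_dose = p$prescription_dose,
                        fraction_size = p$fraction_size,
                        conformation_number = p$meta$conformation_number,
                        below_floor = p$meta$below_floor)))
    jsonlite::write_json(meta, file.path(pdir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    for (tech in names(case$plans)) {
      tag <- gsub("3D-CRT", "3DCRT", tech, fixed = TRUE)
      for (st in names(case$plans[[tech]]$structures))
        write_dvh_csv(case$plans[[tech]]$structures[[st]],
                      file.path(pdir, sprintf("%s_%s.csv", tag, st)))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(pdirs) == 0L)
    stop("no patient sub-directories under ", dir, call. = FALSE)
  cases <- lapply(pdirs, function(pdir) {
    meta <- jsonlite::read_json(file.path(pdir, "meta.json"),
                                simplifyVector = TRUE)
    plans <- lapply(meta$plans, function(pm) {
      tag <- gsub("3D-CRT", "3DCRT", pm$technique, fixed = TRUE)
      files <- list.files(pdir, pattern = paste0("^", tag, "_.*\\.csv$"),
                          full.names = TRUE)
      dvhs <- lapply(files, read_dvh_csv)
      names(dvhs) <- sub(paste0("^", tag, "_"), "", sub("\\.csv$", "", basename(files)))
      rt_plan(pm$technique, pm$prescription_dose, dvhs,
              fraction_size = pm$fraction_size,
              meta = list(conformation_number = pm$conformation_number,
                          below_floor = isTRUE(pm$below_floor)))
    })
    names(plans) <- vapply(plans, function(p) p$technique, character(1))
    structure(list(id = meta$id, patient_seed = meta$patient_seed,
                   tumor_side = meta$tumor_side, involved = meta$involved,
                   ln_all_el = meta$ln_all_el, ln_adj_el = meta$ln_adj_el,
                   gtv_radius = meta$gtv_radius, ptv_radius = meta$ptv_radius,
                   plans = plans),
              class = "patient_case")
  })
  structure(cases, class = "ln_cohort")
}
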