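#' Hilar and mediastinal lymph-node stations
#'
#' The fixed station vocabulary used throughout the package: AJCC hilar and
#' mediastinal stations 1-9 plus the per-side hilar/interlobar levels 10 and
#' 11, which are merged per side (`10_11R`, `10_11L`), as is usual when
#' contouring from a CT-based nodal atlas.
#'
#' @return `ln_stations()`: character vector of the 13 station labels.
#'   `station_side()`: `"right"`, `"left"` or `"midline"` for each label.
#' @examples
#' ln_stations()
#' station_side(c("4R", "5", "7"))
#' @export
ln_stations <- function() {
  c("1", "2R", "2L", "3", "4R", "4L", "5", "6", "7", "8", "9",
    "10_11R", "10_11L")
}

#' @rdname ln_stations
#' @param labels character vector of station labels.
#' @export
station_side <- function(labels) {
  check_stations(labels)
  side <- rep("midline", length(labels))
  side[labels %in% c("2R", "4R", "10_11R")] <- "right"
  # stations 5 (aortopulmonary window) and 6 (para-aortic) are left-sided
  side[labels %in% c("2L", "4L", "5", "6", "10_11L")] <- "left"
  side
}

check_stations <- function(labels, what = "station") {
  bad <- setdiff(labels, ln_stations())
  if (length(bad))
    stop(sprintf("unknown %s label(s): %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  invisible(labels)
}

#' Default station adjacency map
#'
#' Anatomical adjacency between nodal stations, as a named list mapping each
#' station to its direct neighbours (a symmetric graph over the
#' [ln_stations()] vocabulary).  The graph follows the cranio-caudal ordering
#' of a CT-based mediastinal atlas: the paratracheal chains 1-2R-4R and
#' 1-2L-4L, the prevascular station 3 bordering both upper paratracheal
#' levels, the subcarinal hub 7 bordering both lower paratracheal stations
#' and both hila, the aortopulmonary stations 5-6 on the left, and the
#' paraesophageal chain 7-8-9.  It is a modelling choice, not a measured
#' anatomy: real adjacency varies with individual anatomy, and the map can be
#' replaced by any symmetric graph (see `adjacency` argument of
#' [adjacent_elective()]), e.g. one read from JSON with
#' [read_adjacency_json()].
#'
#' The graph deliberately keeps stations 5 and 6 (and hence their edges)
#' left-sided, so it is not mirror-symmetric; contralateral hila are not
#' adjacent to each other.
#'
#' @return Named list: station label -> character vector of neighbours.
#' @export
default_adjacency <- function() {
  edges <- list(
    c("1", "2R"), c("1", "2L"), c("1", "3"),
    c("3", "2R"), c("3", "2L"),
    c("2R", "4R"), c("2L", "4L"),
    c("4R", "4L"), c("4R", "7"), c("4L", "7"),
    c("4L", "5"), c("5", "6"),
    c("7", "8"), c("8", "9"),
    c("4R", "10_11R"), c("4L", "10_11L"),
    c("5", "10_11L"),
    c("7", "10_11R"), c("7", "10_11L"))
  adjacency_from_edges(edges)
}

# Build a symmetric named adjacency list covering the whole vocabulary.
adjacency_from_edges <- function(edges) {
  adj <- stats::setNames(vector("list", length(ln_stations())), ln_stations())
  adj[] <- list(character(0))
  for (e in edges) {
    check_stations(e, "adjacency")
    adj[[e[1]]] <- union(adj[[e[1]]], e[2])
    adj[[e[2]]] <- union(adj[[e[2]]], e[1])
  }
  adj
}

validate_adjacency <- function(adjacency) {
  if (!is.list(adjacency) || is.null(names(adjacency)))
    stop("configuration error: adjacency must be a named list", call. = FALSE)
  check_stations(names(adjacency), "adjacency")
  check_stations(unlist(adjacency, use.names = FALSE), "adjacency")
  missing <- setdiff(ln_stations(), names(adjacency))
  if (length(missing))
    stop(sprintf("configuration error: adjacency map lacks station(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(adjacency)
}

#' Nodal involvement case
#'
#' Records which stations contain macroscopic (PET-positive) disease and the
#' laterality of the primary tumour; the grouping rules
#' [all_elective()] / [adjacent_elective()] operate on this.
#'
#' @param involved character vector of involved station labels (may be
#'   empty).
#' @param tumor_side `"left"` or `"right"`.
#' @return An object of class `nodal_case`.
#' @examples
#' nodal_case(c("4R", "7"), "right")
#' @export
nodal_case <- function(involved, tumor_side) {
  involved <- unique(as.character(involved))
  check_stations(involved, "involved station")
  tumor_side <- match.arg(tumor_side, c("left", "right"))
  structure(list(involved = involved, tumor_side = tumor_side),
            class = "nodal_case")
}

#' @export
print.nodal_case <- function(x, ...) {
  cat(sprintf("<nodal_case> %s-sided tumour; involved: %s\n", x$tumor_side,
              if (length(x$involved)) paste(x$involved, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Elective (out-of-field) station groupings
#'
#' `all_elective()` returns every uninvolved station — the merged volume of
#' all elective hilar and mediastinal levels outside the CTV.
#'
#' `adjacent_elective()` returns the restricted elective volume: level 7
#' (infracarinal) if uninvolved, the ipsilateral hilum (`10_11R` or `10_11L`)
#' if uninvolved, and every uninvolved station directly adjacent to an
#' involved one.  With only `4R` involved in a right-sided case this yields
#' `{2R, 4L, 7, 10_11R}` under the default adjacency.  The result is always a
#' subset of `all_elective()`.
#'
#' @param case a [nodal_case()].
#' @param adjacency a named adjacency list covering the vocabulary; defaults
#'   to [default_adjacency()].
#' @return Character vector of station labels, in vocabulary order.
#' @examples
#' adjacent_elective(nodal_case("4R", "right"))
#' @export
all_elective <- function(case) {
  stopifnot(inherits(case, "nodal_case"))
  setdiff(ln_stations(), case$involved)
}

#' @rdname all_elective
#' @export
adjacent_elective <- function(case, adjacency = default_adjacency()) {
  stopifnot(inherits(case, "nodal_case"))
  validate_adjacency(adjacency)
  hilum <- if (case$tumor_side == "right") "10_11R" else "10_11L"
  neighbours <- unique(unlist(adjacency[case$involved], use.names = FALSE))
  members <- setdiff(union(c("7", hilum), neighbours), case$involved)
  intersect(ln_stations(), members)
}

# Mirror a station label (R <-> L); midline and left-only stations unchanged.
mirror_station <- function(labels) {
  map <- c("2R" = "2L", "2L" = "2R", "4R" = "4L", "4L" = "4R",
           "10_11R" = "10_11L", "10_11L" = "10_11R")
  out <- labels
  hit <- labels %in% names(map)
  out[hit] <- map[labels[hit]]
  out
}

mirror_case <- function(case) {
  nodal_case(mirror_station(case$involved),
             if (case$tumor_side == "right") "left" else "right")
}

mirror_adjacency <- function(adjacency) {
  out <- lapply(adjacency, mirror_station)
  stats::setNames(out, mirror_station(names(adjacency)))[names(adjacency)]
}

#' Merge station masks into one region of interest
#'
#' Voxelwise union of the masks of the given stations; DVHs of a grouped
#' nodal volume are computed on this merged mask, never as volume-weighted
#' averages of per-station DVHs (overlapping stations would otherwise be
#' double counted).
#'
#' @param stations character vector of station labels (non-empty).
#' @param masks named list of [structure_mask()] objects containing at least
#'   the requested stations; all congruent.
#' @param name label for the merged structure.
#' @return A [structure_mask()].
#' @export
merge_station_volumes <- function(stations, masks, name = "merged") {
  stations <- as.character(stations)
  if (length(stations) == 0L)
    stop("structure-empty error: no stations to merge", call. = FALSE)
  check_stations(stations)
  missing <- setdiff(stations, names(masks))
  if (length(missing))
    stop(sprintf("configuration error: no mask for station(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  acc <- masks[[stations[1]]]$mask
  for (s in stations[-1]) {
    m <- masks[[s]]$mask
    if (!identical(dim(m), dim(acc)))
      stop("geometry error: station masks are not congruent", call. = FALSE)
    acc <- acc | m
  }
  structure_mask(name, acc)
}
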