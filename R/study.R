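#' Study configuration
#'
#' Bundles everything [run_study()] needs: the radiobiological parameters,
#' the generator configuration (or a cohort directory to analyse instead),
#' and the output location.  All validation happens here, before any
#' computation.
#'
#' @param seed master seed; mandatory when simulating, ignored (and
#'   forbidden to matter) when analysing a fixed cohort directory.
#' @param n_patients cohort size for simulation.
#' @param params a [radiobio_params()].
#' @param generator a [synth_config()]; built from `seed`/`n_patients` when
#'   omitted.
#' @param input_dir optional cohort directory written by [write_cohort()];
#'   when given, no simulation is performed.
#' @param out_dir optional output directory for result CSVs and the run
#'   manifest.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = NULL, n_patients = 41,
                         params = radiobio_params(),
                         generator = NULL, input_dir = NULL, out_dir = NULL) {
  stopifnot(inherits(params, "radiobio_params"))
  if (is.null(input_dir)) {
    if (is.null(generator)) {
      if (is.null(seed))
        stop("config error: `seed` is required when simulating a cohort",
             call. = FALSE)
      generator <- synth_config(seed = seed, n_patients = n_patients)
    }
    stopifnot(inherits(generator, "synth_config"))
  } else {
    if (!dir.exists(input_dir))
      stop("config error: input_dir does not exist: ", input_dir, call. = FALSE)
    generator <- NULL
  }
  structure(list(params = params, generator = generator,
                 input_dir = input_dir, out_dir = out_dir),
            class = "study_config")
}

#' Run the full incidental-dose study
#'
#' Orchestrates the pipeline: obtain a paired cohort (simulate via
#' [generate_cohort()] or load with [read_cohort()]), build the third plan
#' per patient by normalizing each IMRT plan to its paired 3D-CRT
#' prescription ([normalize_plan()]), score the two merged elective nodal
#' volumes under all three plans (mean dose, EUD, TCP), collect PTV metrics
#' (prescription, Dmean, D90, conformation number) and the usual OAR metrics
#' (lung Dmean/V20; esophagus Dmean/V60/V50/Dmax; cord Dmax; heart V60/V45),
#' and summarise the cohort with paired tests via [summarize_cohort()].
#'
#' @param config a [study_config()].
#' @return A list of class `ln_study`: `per_patient` (long nodal metrics;
#'   TCP in %), `ptv` and `oar` (wide per-patient tables), `summary` (a
#'   `cohort_summary`), `prescriptions` (per-patient doses with the paired
#'   comparison as attribute `test`), and `manifest`.  When `out_dir` is
#'   set, result CSVs and a JSON manifest (seed, parameters, config hash,
#'   package version) are also written there.
#' @examples
#' \donttest{
#' st <- run_study(study_config(seed = 1, n_patients = 3))
#' st$summary
#' }
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  params <- config$params
  cohort <- if (is.null(config$input_dir)) generate_cohort(config$generator)
            else read_cohort(config$input_dir)

  per_patient <- list()
  ptv_rows <- list()
  oar_rows <- list()
  rx_rows <- list()

  for (case in cohort) {
    pid <- case$id
    imrt <- case$plans[["IMRT"]]
    crt <- case$plans[["3D-CRT"]]
    if (is.null(imrt) || is.null(crt))
      stop(sprintf("patient %s: missing paired IMRT/3D-CRT plans", pid),
           call. = FALSE)
    norm <- normalize_plan(imrt, crt$prescription_dose)
    three <- list("IMRT" = imrt, "IMRT_norm" = norm, "3D-CRT" = crt)

    for (pl in names(three)) {
      plan <- three[[pl]]
      for (vol in c("LN_all_el", "LN_adj_el")) {
        dvh <- plan$structures[[vol]]
        if (is.null(dvh))
          stop(sprintf("patient %s: plan %s lacks a DVH for %s", pid, pl, vol),
               call. = FALSE)
        per_patient[[length(per_patient) + 1L]] <- data.frame(
          patient = pid, plan = pl, volume = vol,
          metric = c("Dmean", "EUD", "TCP"),
          value = c(metric_mean(dvh), eud(dvh, params$a),
                    100 * tcp_from_dvh(dvh, params)),
          stringsAsFactors = FALSE)
      }
      ptv_dvh <- plan$structures[["ptv"]]
      ptv_rows[[length(ptv_rows) + 1L]] <- data.frame(
        patient = pid, plan = pl,
        prescription = plan$prescription_dose,
        ptv_dmean = metric_mean(ptv_dvh), ptv_d90 = metric_Dx(ptv_dvh, 90),
        conformation_number = if (is.null(plan$meta$conformation_number))
          NA_real_ else plan$meta$conformation_number,
        below_floor = isTRUE(plan$meta$below_floor),
        stringsAsFactors = FALSE)
      s <- plan$structures
      oar_rows[[length(oar_rows) + 1L]] <- data.frame(
        patient = pid, plan = pl,
        lung_dmean = metric_mean(s$lung), lung_v20 = metric_Vx(s$lung, 20),
        eso_dmean = metric_mean(s$esophagus),
        eso_v60 = metric_Vx(s$esophagus, 60),
        eso_v50 = metric_Vx(s$esophagus, 50),
        eso_dmax = metric_max(s$esophagus),
        cord_dmax = metric_max(s$spinal_cord),
        heart_v60 = metric_Vx(s$heart, 60), heart_v45 = metric_Vx(s$heart, 45),
        stringsAsFactors = FALSE)
    }
    rx_rows[[length(rx_rows) + 1L]] <- data.frame(
      patient = pid, rx_imrt = imrt$prescription_dose,
      rx_3dcrt = crt$prescription_dose, stringsAsFactors = FALSE)
  }

  per_patient <- do.call(rbind, per_patient)
  per_patient <- per_patient[order(per_patient$patient, per_patient$plan,
                                   per_patient$volume, per_patient$metric), ]
  rownames(per_patient) <- NULL
  ptv <- do.call(rbind, ptv_rows)
  oar <- do.call(rbind, oar_rows)
  prescriptions <- do.call(rbind, rx_rows)
  if (nrow(prescriptions) >= 2L)
    attr(prescriptions, "test") <- paired_compare(prescriptions$rx_imrt,
                                                  prescriptions$rx_3dcrt,
                                                  label = "prescription dose")
  summary <- summarize_cohort(per_patient)

  manifest <- list(
    package = "incidose",
    version = as.character(utils::packageVersion("incidose")),
    r_version = as.character(getRversion()),
    seed = if (is.null(config$generator)) NA else config$generator$seed,
    n_patients = length(cohort),
    params = unclass(params),
    generator = if (is.null(config$generator)) NULL
                else unclass(config$generator),
    input_dir = config$input_dir,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  manifest$config_hash <- config_hash(manifest[c("seed", "n_patients",
                                                 "params", "generator")])

  out <- structure(list(per_patient = per_patient, ptv = ptv, oar = oar,
                        prescriptions = prescriptions, summary = summary,
                        manifest = manifest),
                   class = "ln_study")
  if (!is.null(config$out_dir)) write_study(out, config$out_dir)
  out
}

# md5 of the canonical JSON serialization of the run-defining settings
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$per_patient, file.path(dir, "per_patient.csv"),
                   row.names = FALSE)
  utils::write.csv(study$ptv, file.path(dir, "ptv_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(study$oar, file.path(dir, "oar_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(study$prescriptions, file.path(dir, "prescriptions.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summary$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(study$summary$tests))
    utils::write.csv(study$summary$tests, file.path(dir, "paired_tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.ln_study <- function(x, ...) {
  cat(sprintf("<ln_study> %d patients (config %s)\n",
              x$manifest$n_patients, x$manifest$config_hash))
  rx <- x$prescriptions
  cat(sprintf("  prescriptions: IMRT %.1f +/- %.1f Gy vs 3D-CRT %.1f +/- %.1f Gy",
              mean(rx$rx_imrt), stats::sd(rx$rx_imrt),
              mean(rx$rx_3dcrt), stats::sd(rx$rx_3dcrt)))
  tst <- attr(rx, "test")
  if (!is.null(tst)) cat(sprintf(" (p = %.3g, %s)", tst$p_value, tst$test_used))
  cat("\n\n")
  print(x$summary)
  invisible(x)
}
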