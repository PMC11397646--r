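# Table readers with row-level validation, run configuration, and the
# end-to-end pipeline assembling classification, mutarotation fitting and
# equilibrium thermodynamics into one per-compound report.

#' Run configuration for the analysis pipeline
#'
#' @param rt_mode RT handling, `"paper_rounded"` or `"exact"`; see
#'   [thermo_constants()].
#' @param a_value_kcal A-value (kcal/mol) used for anomeric
#'   stabilization; default 1.25 (hydroxyl on cyclohexane).  Use 1.93
#'   for the tetrahydropyran-extrapolated value.
#' @param a_ring_system Ring system the A-value refers to.
#' @param reference_beta,reference_alpha Populations of the reference
#'   2-hydroxytetrahydropyran equilibrium against which the
#'   reverse-anomeric-effect magnitude is computed (default 47.1/52.9,
#'   DMSO).
#' @param temperature Kelvin.
#' @param windows Classifier windows, see [classifier_windows()].
#' @param flat_tol Flatness threshold for [fit_equilibration()].
#' @param strict Validation strictness flag passed to readers.
#' @return Object of class `run_config`.
#' @export
run_config <- function(rt_mode = "paper_rounded",
                       a_value_kcal = 1.25,
                       a_ring_system = "cyclohexane",
                       reference_beta = 47.1,
                       reference_alpha = 52.9,
                       temperature = 298,
                       windows = classifier_windows(),
                       flat_tol = 3.5,
                       strict = FALSE) {
  structure(list(rt_mode = rt_mode,
                 a_value_kcal = a_value_kcal,
                 a_ring_system = a_ring_system,
                 reference_beta = reference_beta,
                 reference_alpha = reference_alpha,
                 temperature = temperature,
                 windows = windows,
                 flat_tol = flat_tol,
                 strict = strict),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Settings omitted from the file keep the [run_config()] defaults; the
#' result round-trips through [write_run_config()].
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$windows)) raw$windows <- do.call(classifier_windows,
                                                    raw$windows)
  do.call(run_config, raw)
}

#' Write a run configuration to JSON
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- unclass(config)
  # named atomic vectors lose their names as JSON arrays; emit objects
  payload$windows$one_bond_refs <-
    lapply(payload$windows$one_bond_refs, as.list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

check_columns <- function(df, mandatory, path) {
  names(df) <- tolower(names(df))
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

finish_read <- function(rows, errors, path, strict) {
  n_bad <- nrow(errors)
  n_all <- nrow(rows) + n_bad
  if (n_all > 0 && n_bad > 0.5 * n_all)
    stop("more than half of the rows in ", path, " are invalid")
  if (strict && n_bad > 0)
    stop(n_bad, " invalid row(s) in ", path, "; first: ",
         errors$reason[1])
  attr(rows, "errors") <- errors
  rows
}

#' Read an anomer-equilibrium table
#'
#' Expected columns (case-insensitive): `compound_id`, `solvent`,
#' `temperature_k`, `percent_beta` and optionally `percent_alpha`
#' (auto-filled as the complement when absent or blank).  Invalid rows
#' are collected into the `errors` attribute, never silently dropped.
#'
#' @param path CSV file path.
#' @param strict Abort on any invalid row.
#' @return Data frame of validated rows; attribute `errors` holds a data
#'   frame of `(row, reason)` for rejected rows.
#' @export
read_equilibrium_csv <- function(path, strict = FALSE) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, c("compound_id", "percent_beta"), path)
  if (!"percent_alpha" %in% names(df)) df$percent_alpha <- NA_real_
  if (!"solvent" %in% names(df)) df$solvent <- "unspecified"
  if (!"temperature_k" %in% names(df)) df$temperature_k <- 298
  keep <- logical(nrow(df))
  reasons <- character(0); bad_rows <- integer(0)
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      pa <- df$percent_alpha[i]
      eq <- if (is.na(pa))
        anomer_equilibrium(as.character(df$compound_id[i]),
                           df$percent_beta[i],
                           solvent = as.character(df$solvent[i]),
                           temperature = df$temperature_k[i])
      else
        anomer_equilibrium(as.character(df$compound_id[i]),
                           df$percent_beta[i], pa,
                           solvent = as.character(df$solvent[i]),
                           temperature = df$temperature_k[i])
      df$percent_alpha[i] <- eq$percent_alpha
      TRUE
    }, error = function(e) conditionMessage(e))
    if (isTRUE(res)) keep[i] <- TRUE
    else { bad_rows <- c(bad_rows, i); reasons <- c(reasons, res) }
  }
  finish_read(df[keep, , drop = FALSE],
              data.frame(row = bad_rows, reason = reasons,
                         stringsAsFactors = FALSE),
              path, strict)
}

#' Read a mutarotation time-course table
#'
#' Expected columns: `compound_id`, `solvent`, `time_value`,
#' `time_unit` (`min`, `h` or `d`; converted to hours) and
#' `percent_beta`.  Rows with unknown units or out-of-range percentages
#' are rejected into the `errors` attribute.
#'
#' @inheritParams read_equilibrium_csv
#' @return Data frame with an added `time_h` column; attribute `errors`
#'   as in [read_equilibrium_csv()].
#' @export
read_mutarotation_csv <- function(path, strict = FALSE) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, c("compound_id", "time_value", "time_unit",
                            "percent_beta"), path)
  if (!"solvent" %in% names(df)) df$solvent <- "unspecified"
  unit_h <- c(min = 1 / 60, h = 1, d = 24)
  keep <- logical(nrow(df))
  reasons <- character(0); bad_rows <- integer(0)
  df$time_h <- NA_real_
  for (i in seq_len(nrow(df))) {
    u <- tolower(as.character(df$time_unit[i]))
    pb <- df$percent_beta[i]
    reason <- NULL
    if (!u %in% names(unit_h))
      reason <- paste0("unknown time unit '", u, "'")
    else if (!is.finite(df$time_value[i]) || df$time_value[i] < 0)
      reason <- "negative or non-numeric time"
    else if (!is.finite(pb) || pb <= 0 || pb >= 100)
      reason <- "percent_beta outside (0, 100)"
    if (is.null(reason)) {
      df$time_h[i] <- df$time_value[i] * unit_h[[u]]
      keep[i] <- TRUE
    } else {
      bad_rows <- c(bad_rows, i); reasons <- c(reasons, reason)
    }
  }
  finish_read(df[keep, , drop = FALSE],
              data.frame(row = bad_rows, reason = reasons,
                         stringsAsFactors = FALSE),
              path, strict)
}

#' Read an NMR-observable table
#'
#' One row per species; mandatory column `species_id`, every other field
#' of [nmr_observables()] optional (blank for missing).
#'
#' @inheritParams read_equilibrium_csv
#' @return List of `nmr_observables` objects; attribute `errors` as in
#'   [read_equilibrium_csv()].
#' @export
read_nmr_csv <- function(path, strict = FALSE) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, "species_id", path)
  num <- function(col, i) {
    if (!col %in% names(df)) return(NA_real_)
    v <- suppressWarnings(as.numeric(df[[col]][i]))
    if (length(v) == 0) NA_real_ else v
  }
  out <- list()
  reasons <- character(0); bad_rows <- integer(0)
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(
      nmr_observables(
        species_id = as.character(df$species_id[i]),
        j_h1_h2 = num("j_h1_h2", i),
        one_bond_j_c1_h1 = num("one_bond_j_c1_h1", i),
        delta_c1 = num("delta_c1", i),
        j_ch_eq_ch = num("j_ch_eq_ch", i),
        j_ch_chn = num("j_ch_chn", i),
        optical_rotation_d = num("optical_rotation_d", i),
        rotation_solvent = if ("rotation_solvent" %in% names(df))
          as.character(df$rotation_solvent[i]) else NA_character_,
        acetylated = if ("acetylated" %in% names(df))
          isTRUE(as.logical(df$acetylated[i])) else FALSE),
      error = function(e) conditionMessage(e))
    if (inherits(res, "nmr_observables")) out[[length(out) + 1L]] <- res
    else { bad_rows <- c(bad_rows, i); reasons <- c(reasons, res) }
  }
  errors <- data.frame(row = bad_rows, reason = reasons,
                       stringsAsFactors = FALSE)
  if (nrow(df) > 0 && nrow(errors) > 0.5 * nrow(df))
    stop("more than half of the rows in ", path, " are invalid")
  if (strict && nrow(errors) > 0)
    stop(nrow(errors), " invalid row(s) in ", path)
  attr(out, "errors") <- errors
  out
}

#' Read a torsion-scan table
#'
#' Expected columns: `angle_deg`, `energy_kcal`.
#'
#' @param path CSV file path.
#' @return A [torsion_profile()].
#' @export
read_torsion_csv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, c("angle_deg", "energy_kcal"), path)
  torsion_profile(df$angle_deg, df$energy_kcal)
}

#' Run the full anomeric-effect analysis pipeline
#'
#' For each compound: optionally classify its NMR observables, fit the
#' mutarotation time course (or take the supplied equilibrium), then
#' compute K_an, the anomerization free energy, the anomeric
#' stabilization in both cyclohexane- and tetrahydropyran-referenced
#' modes, and the reverse-anomeric-effect magnitude against the
#' configured reference equilibrium.  A failing compound is reported in
#' `$errors` without aborting the rest of the run; results are
#' deterministic given inputs and configuration.
#'
#' @param config A [run_config()].
#' @param equilibria Data frame as returned by [read_equilibrium_csv()]
#'   (or `NULL`).
#' @param series List of [mutarotation_series()] objects (or `NULL`).
#' @param nmr List of [nmr_observables()] objects (or `NULL`).
#' @return Object of class `pipeline_report`: list with `results` (data
#'   frame, one row per compound), `anomer_calls`, `fits`, `errors`,
#'   and `config`.
#' @export
#' @examples
#' eq <- data.frame(compound_id = "121", solvent = "DMSO-d6",
#'                  temperature_k = 298, percent_beta = 47.1,
#'                  percent_alpha = 52.9)
#' run_pipeline(run_config(), equilibria = eq)
run_pipeline <- function(config, equilibria = NULL, series = NULL,
                         nmr = NULL) {
  stopifnot(inherits(config, "run_config"))
  constants <- thermo_constants(config$rt_mode)
  a_cy <- a_value("OH", config$a_value_kcal, config$a_ring_system)
  a_thp <- if (a_cy$ring_system == "cyclohexane")
    a_value_cyclohexane_to_thp(a_cy) else a_cy
  ref_eq <- anomer_equilibrium("reference", config$reference_beta,
                               config$reference_alpha,
                               solvent = "DMSO-d6",
                               temperature = config$temperature)
  e_an_ref <- anomeric_stabilization(ref_eq, a_cy, constants)

  calls <- list()
  if (!is.null(nmr))
    for (obs in nmr)
      calls[[obs$species_id]] <- tryCatch(
        classify_anomer(obs, config$windows), error = function(e) e)

  fits <- list()
  errors <- character(0)
  rows <- list()

  add_equilibrium_row <- function(compound_id, solvent, temperature,
                                  percent_beta, percent_alpha = NULL,
                                  source) {
    tryCatch({
      eq <- if (is.null(percent_alpha))
        anomer_equilibrium(compound_id, percent_beta, solvent = solvent,
                           temperature = temperature)
      else
        anomer_equilibrium(compound_id, percent_beta, percent_alpha,
                           solvent = solvent, temperature = temperature)
      st_cy <- anomeric_stabilization(eq, a_cy, constants)
      st_thp <- anomeric_stabilization(eq, a_thp, constants)
      rae <- rae_magnitude(e_an_ref, st_cy)
      call <- calls[[compound_id]]
      rows[[length(rows) + 1L]] <<- data.frame(
        compound_id = compound_id,
        solvent = solvent,
        source = source,
        anomer_call = if (inherits(call, "anomer_call")) call$call
                      else NA_character_,
        percent_beta = eq$percent_beta,
        k_an = k_an(eq),
        dg_an_kcal = st_cy$dg_an,
        e_an_kcal = st_cy$e_an,
        e_an_thp_kcal = st_thp$e_an,
        dg_rae_kcal = rae$dg_rae,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      errors <<- c(errors, paste0(compound_id, ": ", conditionMessage(e)))
    })
    invisible(NULL)
  }

  if (!is.null(equilibria) && nrow(equilibria) > 0) {
    names(equilibria) <- tolower(names(equilibria))
    for (i in seq_len(nrow(equilibria))) {
      pa <- if ("percent_alpha" %in% names(equilibria))
        equilibria$percent_alpha[i] else NULL
      if (!is.null(pa) && is.na(pa)) pa <- NULL
      add_equilibrium_row(
        as.character(equilibria$compound_id[i]),
        if ("solvent" %in% names(equilibria))
          as.character(equilibria$solvent[i]) else "unspecified",
        if ("temperature_k" %in% names(equilibria))
          equilibria$temperature_k[i] else config$temperature,
        equilibria$percent_beta[i], pa, source = "equilibrium")
    }
  }

  if (!is.null(series))
    for (s in series) {
      res <- tryCatch({
        fit <- fit_equilibration(s, config$flat_tol)
        fits[[s$compound_id]] <- fit
        add_equilibrium_row(s$compound_id, s$solvent, config$temperature,
                            fit$beta_eq, source = "mutarotation_fit")
        TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(res))
        errors <- c(errors, paste0(s$compound_id, ": ", res))
    }

  results <- if (length(rows)) do.call(rbind, rows)
    else data.frame(compound_id = character(), solvent = character(),
                    source = character(), anomer_call = character(),
                    percent_beta = numeric(), k_an = numeric(),
                    dg_an_kcal = numeric(), e_an_kcal = numeric(),
                    e_an_thp_kcal = numeric(), dg_rae_kcal = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(results) == 0)
    warning("pipeline produced an empty report (no valid inputs)")

  structure(list(results = results, anomer_calls = calls, fits = fits,
                 errors = errors, config = config,
                 e_an_reference = e_an_ref$e_an),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d compound(s), reference E_an = %.2f kcal/mol\n",
              nrow(x$results), x$e_an_reference))
  if (nrow(x$results)) {
    shown <- x$results
    num <- vapply(shown, is.numeric, logical(1))
    shown[num] <- lapply(shown[num], round, 3)
    print(shown, row.names = FALSE)
  }
  if (length(x$errors))
    cat("errors:\n ", paste(x$errors, collapse = "\n  "), "\n")
  invisible(x)
}

#' Write a pipeline report to CSV and JSON
#'
#' The CSV carries the per-compound table rounded for display (2 dp on
#' kcal/mol quantities); the JSON carries full precision plus a
#' provenance block (package version and configuration).
#'
#' @param report A [run_pipeline()] result.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisible list of paths written.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!is.null(csv_path)) {
    out <- report$results
    kcal <- grep("kcal", names(out))
    out[kcal] <- lapply(out[kcal], round, 2)
    out$k_an <- round(out$k_an, 4)
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- list(
      provenance = list(
        package = "anomeric",
        version = as.character(utils::packageVersion("anomeric")),
        config = unclass(report$config)),
      e_an_reference = report$e_an_reference,
      results = report$results,
      errors = report$errors)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}
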