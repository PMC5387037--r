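#' Load a simulation/estimation scenario from a YAML config
#'
#' Reads a flat YAML file with two nested blocks, `photo` and `resistance`,
#' plus optional top-level keys `ci_grid` (`start`/`stop`/`step`, ubar),
#' `o2_levels` (mbar), `noise_sd` (umol m^-2 s^-1) and `seed`. Defaults are
#' applied and announced on standard error: `O = 210` mbar when the photo
#' block omits it, and `rsc = 1/gm_dif` when the resistance block omits it.
#' All validation failures are collected and reported together.
#'
#' @param path Path to the YAML file.
#' @return An object of class `"scenario_config"`: list with `photo`
#'   ([photo_params()]), `resistance` ([resistance_params()]), `ci`
#'   (numeric grid), `o2_levels`, `noise_sd`, `seed`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "mesoflux_validation_error")
  }
  cfg <- yaml::read_yaml(path)
  errs <- character()
  note <- function(msg) inform(paste0("[mesoflux config] ", msg))

  ph <- cfg$photo
  if (is.null(ph)) {
    errs <- c(errs, "missing `photo` block")
  } else {
    need <- c("Vcmax", "J", "Rd", "KmC", "KmO", "Sco")
    miss <- setdiff(need, names(ph))
    if (length(miss)) {
      errs <- c(errs, paste0("photo block missing: ",
                             paste(miss, collapse = ", ")))
    }
    if (is.null(ph$O)) {
      ph$O <- 210
      note("photo$O not given; defaulting to ambient 210 mbar")
    }
  }
  rs <- cfg$resistance
  if (is.null(rs)) {
    errs <- c(errs, "missing `resistance` block")
  } else {
    if (is.null(rs$gm_dif)) errs <- c(errs, "resistance block missing: gm_dif")
    if (is.null(rs$omega)) errs <- c(errs, "resistance block missing: omega")
    if (is.null(rs$sigma) && is.null(rs$lambda)) {
      errs <- c(errs, "resistance block needs `sigma` or `lambda`")
    }
    if (is.null(rs$rsc) && !is.null(rs$gm_dif)) {
      note(sprintf("resistance$rsc not given; defaulting to 1/gm_dif = %g",
                   1 / rs$gm_dif))
    }
  }
  grid <- NULL
  if (!is.null(cfg$ci_grid)) {
    g <- cfg$ci_grid
    if (any(vapply(list(g$start, g$stop, g$step), is.null, logical(1)))) {
      errs <- c(errs, "ci_grid needs start, stop and step")
    } else if (g$start <= 0 || g$step <= 0 || g$stop < g$start) {
      errs <- c(errs, "ci_grid must have start > 0, step > 0, stop >= start")
    } else {
      grid <- seq(g$start, g$stop, by = g$step)
    }
  }
  noise_sd <- cfg$noise_sd %||% 0
  if (noise_sd < 0) errs <- c(errs, "noise_sd must be >= 0")

  photo <- resistance <- NULL
  if (!length(errs)) {
    photo <- tryCatch(
      photo_params(ph$Vcmax, ph$J, ph$Rd, ph$KmC, ph$KmO, ph$Sco, O = ph$O),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    resistance <- tryCatch(
      resistance_params(rs$gm_dif, rs$omega, sigma = rs$sigma,
                        lambda = rs$lambda, k = rs$k, rsc = rs$rsc),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  }
  if (length(errs)) {
    abort(paste0("Invalid scenario config:\n  - ",
                 paste(errs, collapse = "\n  - ")),
          class = "mesoflux_validation_error")
  }
  structure(list(photo = photo, resistance = resistance, ci = grid,
                 o2_levels = cfg$o2_levels %||% photo$O,
                 noise_sd = noise_sd, seed = cfg$seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  print(x$photo)
  print(x$resistance)
  if (!is.null(x$ci)) {
    cat(sprintf("  ci grid: %g..%g ubar (%d points)\n",
                min(x$ci), max(x$ci), length(x$ci)))
  }
  cat(sprintf("  o2_levels: %s mbar; noise_sd = %g; seed = %s\n",
              paste(x$o2_levels, collapse = ", "), x$noise_sd,
              x$seed %||% "none"))
  invisible(x)
}

curve_cols <- c("ci_ubar", "cc_ubar", "cm_outer_ubar", "a_umol", "vc_umol",
                "f_umol", "limitation", "gm_app")

#' Write / read a simulated A-Ci curve as CSV
#'
#' The CSV carries the fixed, unit-suffixed header of [operating_point()]
#' output; reading is header-keyed, so column order in the file does not
#' matter. Full numeric precision is preserved on the round trip.
#'
#' @param points A tibble from [operating_point()] / [simulate_aci()].
#' @param path Output file path.
#' @return `write_aci_curve()` returns `path` invisibly; `read_aci_curve()`
#'   returns the curve tibble.
#' @export
write_aci_curve <- function(points, path) {
  miss <- setdiff(curve_cols, names(points))
  if (length(miss)) {
    abort(paste0("Curve table missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mesoflux_validation_error")
  }
  readr::write_csv(points[curve_cols], path)
  invisible(path)
}

#' @rdname write_aci_curve
#' @export
read_aci_curve <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(curve_cols, names(x))
  if (length(miss)) {
    abort(paste0("Curve file missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mesoflux_validation_error")
  }
  check_numeric_rows(x, setdiff(curve_cols, "limitation"))
  as_tibble(x)[curve_cols]
}

#' Read gas-exchange records from CSV
#'
#' Header-keyed reader for measurement tables: one record per row with
#' columns `ci_ubar`, `a_umol`, `j_umol`, and optionally `o_mbar`
#' (defaulting to ambient 210 mbar) and `rd_umol` (defaulting to
#' `rd_default`). Malformed numeric cells are reported with their row
#' numbers.
#'
#' @param path CSV path.
#' @param rd_default Day respiration used for tables without `rd_umol`,
#'   umol m^-2 s^-1.
#' @return A tibble of records.
#' @export
read_gas_exchange <- function(path, rd_default = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("ci_ubar", "a_umol", "j_umol")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("Records file missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mesoflux_validation_error")
  }
  if (!("o_mbar" %in% names(x))) {
    inform("[mesoflux] no `o_mbar` column; assuming ambient 210 mbar")
    x$o_mbar <- 210
  }
  if (!("rd_umol" %in% names(x))) {
    if (is.null(rd_default)) {
      abort("No `rd_umol` column and no `rd_default` supplied.",
            class = "mesoflux_validation_error")
    }
    inform(sprintf("[mesoflux] no `rd_umol` column; using rd_default = %g",
                   rd_default))
    x$rd_umol <- rd_default
  }
  check_numeric_rows(x, c(need, "o_mbar", "rd_umol"))
  if (any(x$ci_ubar <= 0) || any(x$j_umol <= 0) || any(x$rd_umol < 0)) {
    bad <- which(x$ci_ubar <= 0 | x$j_umol <= 0 | x$rd_umol < 0)
    abort(paste0("Out-of-range values in row(s): ",
                 paste(bad, collapse = ", ")),
          class = "mesoflux_validation_error")
  }
  as_tibble(x)
}

#' @rdname read_gas_exchange
#' @param records A tibble of gas-exchange records.
#' @export
write_gas_exchange <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

check_numeric_rows <- function(x, cols) {
  for (cl in cols) {
    v <- x[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      abort(sprintf("Malformed values in column `%s`, row(s): %s",
                    cl, paste(bad, collapse = ", ")),
            class = "mesoflux_validation_error")
    }
  }
  invisible(x)
}
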