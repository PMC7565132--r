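## Readers/writers for gel observation tables, report output with a
## metadata header, run configuration, and the synthetic fixture generator.

.gel_schema <- c("name", "d_min_nm", "d_max_nm", "d_avg_nm", "cl", "l_nm", "m_values")

#' Read a gel observation table
#'
#' Reads a comma-separated table of spontaneous-penetration observations.
#' Required columns: `name`, `d_min_nm`, `d_max_nm`, `d_avg_nm` (particle
#' diameters, nm), `cl` (liquid fraction), `l_nm` (repeat-unit length),
#' `m_values` (semicolon-separated coordinations, e.g. `"3;4"`). `cl` and
#' `l_nm` cells may be ranges written `"lo;hi"`. Lines starting with `#`
#' are comments; extra columns are preserved. Each row is validated
#' (positive lengths, `d_min <= d_avg <= d_max`, every `m >= 3`) and
#' rejected with a row-numbered message on failure.
#'
#' @param path Path to the CSV file. The table of literature observations
#'   bundled with the package is at
#'   `system.file("extdata", "table1_gels.csv", package = "gelpen")`.
#' @return A tibble with character `cl`, `l_nm`, `m_values` columns (kept
#'   verbatim so ranges survive a round trip) ready for
#'   [characterize_gels()].
#' @family io
#' @export
read_gel_table <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("No such file: %s", path))
  header <- names(readr::read_csv(path, comment = "#", n_max = 0,
                                  show_col_types = FALSE, progress = FALSE))
  missing_cols <- setdiff(.gel_schema, header)
  if (length(missing_cols)) {
    stop_validation(paste0(
      "Gel table schema error: missing column(s) ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  gels <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      name = readr::col_character(),
      d_min_nm = readr::col_double(),
      d_max_nm = readr::col_double(),
      d_avg_nm = readr::col_double(),
      cl = readr::col_character(),
      l_nm = readr::col_character(),
      m_values = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  if (nrow(gels) == 0) {
    warn("Gel table is empty (header only).")
    return(gels)
  }
  validate_gel_rows(gels)
  gels
}

validate_gel_rows <- function(gels) {
  for (i in seq_len(nrow(gels))) {
    row <- gels[i, ]
    where <- sprintf("row %d (%s)", i, row$name %||% "?")
    cl <- tryCatch(range_midpoint(row$cl), error = function(e) NA_real_)
    l <- tryCatch(range_midpoint(row$l_nm), error = function(e) NA_real_)
    m <- tryCatch(parse_m_values(row$m_values), error = function(e) NA_integer_)
    if (anyNA(c(row$d_min_nm, row$d_max_nm, row$d_avg_nm, cl, l)) || anyNA(m)) {
      stop_validation(sprintf("Non-numeric or unparseable cell in %s.", where))
    }
    if (row$d_min_nm <= 0 || l <= 0) {
      stop_validation(sprintf("Non-positive length in %s.", where))
    }
    if (!(row$d_min_nm <= row$d_avg_nm && row$d_avg_nm <= row$d_max_nm)) {
      stop_validation(sprintf(
        "Diameter ordering violated in %s: need d_min <= d_avg <= d_max.", where
      ))
    }
    if (cl < 0 || cl >= 1) {
      stop_validation(sprintf("Liquid content out of [0, 1) in %s.", where))
    }
    if (any(m < 3)) {
      stop_validation(sprintf("Coordination m < 3 in %s.", where))
    }
  }
  invisible(gels)
}

#' Write a gel observation table
#'
#' Inverse of [read_gel_table()]; plain CSV, no metadata header.
#'
#' @param gels A gel observation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @family io
#' @export
write_gel_table <- function(gels, path) {
  readr::write_csv(gels, path, progress = FALSE)
  invisible(path)
}

#' Write a result table with a metadata comment header
#'
#' Deterministic CSV output (column and row order preserved) preceded by
#' `#`-prefixed metadata lines: package version, the effective
#' configuration, and a timestamp. Reruns with the same configuration
#' differ only in the timestamp line.
#'
#' @param table A data frame (e.g. from [characterize_gels()] or
#'   [tidy()] of a simulation).
#' @param path Output path.
#' @param metadata Named list echoed into the header.
#' @return `path`, invisibly.
#' @family io
#' @export
write_report <- function(table, path, metadata = list()) {
  if (!is.data.frame(table)) stop_validation("`table` must be a data frame.")
  meta <- c(
    list(generator = paste0("gelpen ", as.character(utils::packageVersion("gelpen")))),
    metadata,
    list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  header <- sprintf("# %s: %s", names(meta),
                    vapply(meta, function(v) paste(format(v), collapse = " "), ""))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(table, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic gel observations and simulation configurations
#'
#' Seeded generator of synthetic fixtures for exercising the pipeline:
#' a gel table whose rows are constructed around a drawn "true" mesh size
#' `R_true_nm` so that rows labelled `spontaneous` satisfy the fit
#' criterion and rows labelled `forced` fail it (the two extra columns
#' `label` and `R_true_nm` ride along beyond the standard schema), plus a
#' list of forced-penetration configurations covering the interesting
#' corners: near-unity `eta`, stiffening cases `eta < 1/3`, and chains
#' near the extensibility limit. Identical seeds give identical output.
#'
#' @param seed Integer RNG seed.
#' @param count Number of gel rows (>= 1).
#' @return A list with elements `gels` (tibble) and `configs` (list of
#'   parameter lists for [simulate_penetration()]).
#' @family io
#' @export
generate_fixtures <- function(seed, count = 10) {
  if (count < 1) stop_domain("`count` must be >= 1.")
  withr::with_seed(as.integer(seed), {
    m <- sample(c(3L, 4L), count, replace = TRUE)
    R_true <- round(10^stats::runif(count, 0.5, 3), 1)  # 3 .. 1000 nm
    cl <- round(stats::runif(count, 0.85, 0.99), 3)
    l <- round(R_true / stats::runif(count, 20, 100), 3)  # well below the mesh
    label <- rep(c("spontaneous", "forced"), length.out = count)
    thresh <- R_true / tan(pi / m)  # largest spontaneously admitted diameter
    frac <- ifelse(label == "spontaneous",
                   stats::runif(count, 0.3, 0.9),
                   stats::runif(count, 1.1, 3))
    d_avg <- round(thresh * frac, 2)
    gels <- tibble(
      name = sprintf("synthetic_gel_%02d", seq_len(count)),
      d_min_nm = round(d_avg * 0.5, 2),
      d_max_nm = round(d_avg * 1.5, 2),
      d_avg_nm = d_avg,
      cl = format(cl, trim = TRUE),
      l_nm = format(l, trim = TRUE),
      m_values = ifelse(m == 3, "3;4", "4"),
      label = label,
      R_true_nm = R_true
    )
    configs <- list(
      list(eta = 0.95, kappa = 0.1, xi = 1, steps = 100),   # near-unity eta
      list(eta = 1 / 3, kappa = 0.1, xi = 1, steps = 100),  # penetration at collapse
      list(eta = 0.2, kappa = 0.1, xi = 3, steps = 200),    # stiffened ellipsoid
      list(eta = 0.1, kappa = 0.45, xi = 1, steps = 200),   # near extensibility limit
      list(eta = 0.25, kappa = 0.1, xi = 1, steps = 200,
           f_rup = Inf, f_dis = 2)                          # damage case
    )
    list(gels = gels, configs = configs)
  })
}

#' Read a flat key-value run configuration
#'
#' Flat YAML mapping of parameter overrides (`l_nm`, `cl`, `kappa`, `xi`,
#' `eta`, `steps`, `f_rup`, `f_dis`, `sigfigs`, `temperature_K`, ...).
#' Unknown keys are rejected. Command-line flags override file values,
#' which override defaults.
#'
#' @param path Path to the YAML file, or `NULL` for an empty config.
#' @return A named list.
#' @family io
#' @export
read_run_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop_config(sprintf("No such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(list())
  known <- c("l_nm", "cl", "kappa", "n", "J", "liquid_content", "xi", "eta",
             "rho", "R", "steps", "f_rup", "f_dis", "sigfigs",
             "temperature_K", "seed", "subtract_reference")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop_config(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  cfg
}
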