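#' Read a design table from CSV with a declaration sidecar
#'
#' The CSV dialect is fixed: comma separator, dot decimal, UTF-8, mandatory
#' header `run,<factors...>,<responses...>`. Factor levels, units and
#' response scales live in a YAML sidecar (or equivalent list) so the data
#' file stays purely numeric. Settings off the declared levels, non-numeric
#' responses and duplicate run ids are rejected with the offending rows
#' named.
#'
#' @param path CSV file.
#' @param config Path to a YAML declaration or a list with elements
#'   `factors` (list of `name`, `unit`, `low`, `center`, `high`) and
#'   `responses` (map response name -> `"percent"`/`"fraction"`).
#' @return A design table (see [design_table()]).
#' @export
read_design_csv <- function(path, config) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) abort(paste0("empty file: ", path))
  cfg <- load_design_config(config)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("no data rows in ", path))
  needed <- c("run", cfg$factors$name, names(cfg$responses))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("header of ", path, " lacks declared column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  num <- raw
  for (cn in setdiff(needed, "run")) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]) & raw[[cn]] != "NA")
    if (length(bad) > 0) {
      abort(paste0("non-numeric value in column `", cn, "` at data row(s): ",
                   paste(bad, collapse = ", ")))
    }
    num[[cn]] <- v
  }
  design_table(num[needed], cfg$factors, cfg$responses)
}

load_design_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || !all(c("factors", "responses") %in% names(config))) {
    abort("design config must declare `factors` and `responses`")
  }
  fac <- purrr::map_dfr(config$factors, function(f) {
    needed <- c("name", "low", "center", "high")
    missing_f <- setdiff(needed, names(f))
    if (length(missing_f) > 0) {
      abort(paste0("factor declaration lacks: ", paste(missing_f, collapse = ", ")))
    }
    tibble::tibble(name = f$name, unit = f$unit %||% "",
                   low = as.numeric(f$low), center = as.numeric(f$center),
                   high = as.numeric(f$high))
  })
  responses <- unlist(config$responses)
  list(factors = design_factors(fac$name, fac$unit, fac$low, fac$center, fac$high),
       responses = responses)
}

#' Write a design table to CSV (and optionally its declaration sidecar)
#'
#' @param x A design table.
#' @param path Output CSV.
#' @param config_path Optional YAML sidecar path to write the factor/response
#'   declaration to.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(x, path, config_path = NULL) {
  meta <- design_meta(x)
  cols <- c("run", meta$factors$name, names(meta$responses))
  readr::write_csv(tibble::as_tibble(x)[cols], path)
  if (!is.null(config_path)) {
    cfg <- list(
      factors = purrr::pmap(meta$factors, function(name, unit, low, center, high) {
        list(name = name, unit = unit, low = low, center = center, high = high)
      }),
      responses = as.list(meta$responses)
    )
    yaml::write_yaml(cfg, config_path)
  }
  invisible(path)
}

#' Read or write an extraction curve CSV
#'
#' Curves use the header `time_s,yield`; basis and feed-mass metadata travel
#' in an optional YAML sidecar so the CSV stays a plain two-column table.
#'
#' @param path CSV file.
#' @param metadata_path Optional YAML sidecar (fields such as `basis`,
#'   `feed_mass_g`, `asymptote`).
#' @return `read_curve_csv()`: tibble with `time` and `yield` and any sidecar
#'   fields as attributes.
#' @export
read_curve_csv <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  if (!all(c("time_s", "yield") %in% names(raw))) {
    abort("curve CSV must have header `time_s,yield`")
  }
  out <- tibble::tibble(time = raw$time_s, yield = raw$yield)
  if (any(diff(out$time) <= 0)) abort("curve times must be strictly increasing")
  if (!is.null(metadata_path)) {
    md <- yaml::read_yaml(metadata_path)
    for (nm in names(md)) attr(out, nm) <- md[[nm]]
  }
  out
}

#' @rdname read_curve_csv
#' @param curve Tibble with `time` and `yield`.
#' @export
write_curve_csv <- function(curve, path, metadata_path = NULL) {
  readr::write_csv(tibble::tibble(time_s = curve$time, yield = curve$yield), path)
  if (!is.null(metadata_path)) {
    keep <- setdiff(names(attributes(curve)),
                    c("names", "row.names", "class", "truth", "noise",
                      "fields", "mass_balance"))
    md <- attributes(curve)[keep]
    if (length(md) == 0) md <- list(basis = "unspecified")
    yaml::write_yaml(md, metadata_path)
  }
  invisible(path)
}

pipeline_allowed_keys <- c("design", "design_config", "response", "scale",
                           "anova_order", "bounds", "kinetics", "seed",
                           "out_dir")
kinetics_allowed_keys <- c("model", "curve", "simulate", "fixed", "n_starts")

#' Read and validate a pipeline configuration
#'
#' Unknown keys are rejected outright so typos cannot silently disable a
#' stage.
#'
#' @param path YAML file (or a list, validated in place).
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), pipeline_allowed_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$design)) abort("config must name a `design` (fixture name or CSV path)")
  if (is.null(cfg$response)) abort("config must name a `response`")
  if (!is.null(cfg$kinetics)) {
    unknown_k <- setdiff(names(cfg$kinetics), kinetics_allowed_keys)
    if (length(unknown_k) > 0) {
      abort(paste0("unknown kinetics config key(s): ", paste(unknown_k, collapse = ", ")))
    }
    if (is.null(cfg$kinetics$model)) abort("kinetics config must name a `model`")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$scale <- cfg$scale %||% "percent"
  cfg
}

#' Run the full analysis pipeline from a configuration
#'
#' Ties the stages together: load the design (embedded fixture or CSV), fit
#' the full quadratic surface, write the ANOVA (computed on the fraction
#' scale) and the coefficients on both response scales, maximize the surface
#' over the experimental box, optionally simulate-or-load and fit a kinetic
#' curve, and write a JSON + text report recording the seed and package
#' version. Any stage failure aborts with the stage named.
#'
#' @param config Path to a YAML config or a list (see [read_run_config()]).
#'   Keys: `design` (fixture name or CSV path), `design_config` (sidecar for
#'   CSV designs), `response`, `scale`, `anova_order`, `bounds`
#'   (`lower`/`upper` maps), `kinetics` (`model`, `curve` path or `simulate`
#'   spec, `fixed`, `n_starts`), `seed`, `out_dir`.
#' @return The report, invisibly. Files written to `out_dir` (default
#'   `tempdir()` subdirectory): `anova.csv`, `anova.txt`,
#'   `coefficients.csv`, `report.json`, `report.txt`, `run.log`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir %||% file.path(tempdir(), "sfekin-run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("sfekin ", as.character(utils::packageVersion("sfekin"))),
    paste0("seed: ", cfg$seed)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  design <- stage("load-design", {
    if (cfg$design %in% c("table1", "table3")) {
      sfe_fixture(cfg$design)
    } else {
      read_design_csv(cfg$design, cfg$design_config)
    }
  })
  log_lines <- c(log_lines, paste0("design: ", cfg$design, " (", nrow(design), " runs)"))

  fit_pct <- stage("fit-surface", fit_surface(design, cfg$response, scale = "percent"))
  fit_frac <- rescale_surface(fit_pct, "fraction")
  av <- stage("anova", surface_anova(
    fit_frac, order = cfg$anova_order %||% NULL, scale = "fraction"
  ))
  write_anova_csv(av, file.path(out_dir, "anova.csv"))
  writeLines(format_anova(av), file.path(out_dir, "anova.txt"))

  coefs <- dplyr::bind_rows(
    dplyr::mutate(tidy(fit_pct), scale = "percent"),
    dplyr::mutate(tidy(fit_frac), scale = "fraction")
  )
  readr::write_csv(coefs, file.path(out_dir, "coefficients.csv"))

  opt <- stage("optimize", optimize_surface(
    fit_pct,
    lower = unlist(cfg$bounds$lower) %||% NULL,
    upper = unlist(cfg$bounds$upper) %||% NULL
  ))
  log_lines <- c(log_lines, paste0(
    "optimum (", cfg$response, ", percent): ",
    paste0(fit_pct$factors$name, " = ",
           format(unlist(opt[1, fit_pct$factors$name]), digits = 6),
           " ", fit_pct$factors$unit, collapse = ", "),
    " -> ", format(opt$.fitted[1], digits = 6)
  ))

  report <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("sfekin")),
    design = cfg$design,
    response = cfg$response,
    surface = list(
      r_squared = fit_pct$r_squared,
      coefficients_percent = as.list(setNames(tidy(fit_pct)$estimate, tidy(fit_pct)$term)),
      coefficients_fraction = as.list(setNames(tidy(fit_frac)$estimate, tidy(fit_frac)$term))
    ),
    anova = as.list(tibble::as_tibble(av)),
    optimum = c(
      as.list(opt[1, c(fit_pct$factors$name, ".fitted")]),
      list(active_bounds = unlist(opt[1, paste0(fit_pct$factors$name, "_bound")]))
    )
  )

  if (!is.null(cfg$kinetics)) {
    kin <- cfg$kinetics
    fixed <- stage("kinetics-config", resolve_kinetics_fixed(kin$fixed))
    curve <- stage("kinetics-curve", {
      if (!is.null(kin$curve)) {
        read_curve_csv(kin$curve)
      } else if (!is.null(kin$simulate)) {
        sim <- kin$simulate
        params <- resolve_kinetics_fixed(sim$params)
        simulate_curve(
          kin$model, params,
          times = unlist(sim$times) %||% default_sampling_times(),
          noise = noise_spec(sigma = sim$sigma %||% 0, seed = cfg$seed)
        )
      } else {
        abort("kinetics config needs either `curve` or `simulate`")
      }
    })
    kfit <- stage("kinetics-fit", fit_kinetics(
      curve, kin$model, fixed = fixed,
      n_starts = kin$n_starts %||% 8, seed = cfg$seed
    ))
    unavailable <- setdiff(
      switch(kin$model, sovova = c("kf", "ks"), reverchon = c("Di", "kTM"),
             character(0)),
      names(kfit$derived)
    )
    report$kinetics <- list(
      model = kin$model,
      estimates = kfit$estimates,
      derived = if (length(kfit$derived) > 0) kfit$derived else NULL,
      unavailable = if (length(unavailable) > 0) unavailable else NULL,
      sse = kfit$sse, r_squared = kfit$r_squared,
      converged = kfit$converged, seed = kfit$seed
    )
    log_lines <- c(log_lines, paste0(
      "kinetics (", kin$model, "): ",
      paste0(names(unlist(kfit$estimates)), " = ",
             format(unlist(kfit$estimates), digits = 6), collapse = ", "),
      "; R2 = ", format(kfit$r_squared, digits = 6)
    ))
    if (length(unavailable) > 0) {
      log_lines <- c(log_lines, paste0(
        "kinetics: physical coefficients unavailable without bed/particle data: ",
        paste(unavailable, collapse = ", ")))
    }
  }

  stage("report", {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(render_report(report), file.path(out_dir, "report.txt"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  })
  invisible(report)
}

# turn YAML-friendly kinetic parameter specs into live objects
resolve_kinetics_fixed <- function(fixed) {
  if (is.null(fixed)) return(list())
  if (!is.null(fixed$bed)) {
    fixed$bed <- if (identical(fixed$bed, "default")) default_bed() else {
      do.call(bed_properties, fixed$bed)
    }
  }
  if (!is.null(fixed$geometry)) {
    fixed$geometry <- do.call(particle_geometry, fixed$geometry)
  }
  fixed
}

render_report <- function(report, indent = "") {
  out <- character(0)
  for (nm in names(report)) {
    v <- report[[nm]]
    if (is.list(v)) {
      out <- c(out, paste0(indent, nm, ":"), render_report(v, paste0(indent, "  ")))
    } else {
      val <- if (is.numeric(v)) paste(signif(v, 6), collapse = ", ")
             else paste(v, collapse = ", ")
      out <- c(out, paste0(indent, nm, ": ", val))
    }
  }
  out
}
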