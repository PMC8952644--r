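#' Read a two-column decay file
#'
#' Reads delimited text with columns (time in ns, value); `#`-prefixed
#' comment lines and an optional header row are skipped. The time axis must
#' be strictly increasing and uniformly spaced (relative tolerance 1e-6) and
#' values must be non-negative; violations raise parse errors with the
#' offending row.
#'
#' @param path File path.
#' @param kind Curve kind; `NULL` guesses `"counts"` for integer-valued
#'   files, `"model"` otherwise.
#' @return A [decay_curve] with columns `time_ns`, `value`.
#' @export
read_decay_file <- function(path, kind = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (!length(body)) {
    abort(sprintf("no data rows in '%s'.", path),
          class = "fretsphere_parse_error")
  }
  first <- strsplit(trimws(body[1]), "[,;[:space:]]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- tryCatch(
    if (has_header) read.table(text = body, header = TRUE, sep = "")
    else read.table(text = body, header = FALSE, sep = ""),
    error = function(e) {
      abort(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
            class = "fretsphere_parse_error")
    })
  if (ncol(df) < 2) {
    abort(sprintf("'%s': expected two columns (time_ns, value).", path),
          class = "fretsphere_parse_error")
  }
  names(df)[1:2] <- c("time_ns", "value")
  df <- df[, 1:2]
  if (any(df$value < 0)) {
    abort(sprintf("'%s': negative value at row %d.", path,
                  which(df$value < 0)[1]),
          class = "fretsphere_parse_error")
  }
  validate_time_axis(df$time_ns)
  kind <- kind %||%
    (if (all(df$value == round(df$value))) "counts" else "model")
  new_decay_curve(as_tibble(df), kind = kind, meta = list(path = path))
}

#' Write a decay curve as two-column text
#'
#' Full-precision (17 significant digits) tab-delimited output with a `#`
#' comment header; [read_decay_file()] round-trips losslessly.
#'
#' @param curve A [decay_curve].
#' @param path Output path.
#' @param value Value column to write (default auto-detect).
#' @return `path`, invisibly.
#' @export
write_decay_file <- function(curve, path, value = NULL) {
  value <- value %||% value_column(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fretsphere decay curve",
               sprintf("# kind: %s; value: %s", attr(curve, "kind"), value),
               "time_ns\tvalue"), con)
  writeLines(paste(format(curve$time_ns, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   format(curve[[value]], digits = 17, scientific = TRUE,
                          trim = TRUE), sep = "\t"), con)
  invisible(path)
}

# convert *_A (Angstrom) keys to nm at the config boundary
normalize_units <- function(section) {
  if (is.null(section)) return(section)
  nm <- names(section)
  ang <- grepl("_A$", nm)
  for (i in which(ang)) {
    new <- sub("_A$", "", nm[i])
    section[[new]] <- angstrom_to_nm(section[[i]])
    section[[nm[i]]] <- NULL
  }
  names(section) <- sub("_nm$|_ns$", "", names(section))
  section
}

config_section <- function(config, name, builder, defaults = list()) {
  sec <- normalize_units(config[[name]] %||% list())
  do.call(builder, modifyList(defaults, sec))
}

#' Run a configured pipeline stage
#'
#' Executes one or more stages (`"analytic"`, `"simulate"`, `"generate"`,
#' `"fit"`, `"stats"`) from a single shared configuration (a named list, or a
#' path to a JSON file). Every output file is written alongside a JSON
#' provenance record embedding the configuration, seed and package version,
#' so identical configurations reproduce identical outputs.
#'
#' Config sections: `photophysics`, `labeling`, `size` (fields named as the
#' constructor arguments, `_nm`/`_ns` suffixes optional, `_A` accepted for
#' Angstrom), `histogram` (`k_max`, `T_ns`), `engine` (`n_configs`,
#' `n_traj`), `tcspc` (`total_counts`, `background`, `irf_fwhm`), `fit`
#' (`input`, `free`, `model`, `irf_fwhm`), plus `stage`, `seed`, `out_dir`.
#' Unknown section names are rejected.
#'
#' @param config Named list or JSON file path.
#' @param out_dir Output directory (overrides `config$out_dir`; default
#'   `"."`).
#' @param seed Seed override.
#' @return Invisible named list of produced artifacts (objects and file
#'   paths).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  known <- c("stage", "seed", "out_dir", "photophysics", "labeling", "size",
             "histogram", "engine", "tcspc", "fit")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("unknown config section(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "fretsphere_config_error")
  }
  out_dir <- out_dir %||% config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- seed %||% config$seed %||% 1L
  set.seed(seed)

  params <- config_section(config, "photophysics", photophysics_params)
  dist <- config_section(config, "size", size_distribution)
  hist_cfg <- modifyList(list(k_max = 4096L, T_ns = 10 * params$tau0D),
                         config$histogram %||% list())
  eng <- modifyList(list(n_configs = 100L, n_traj = 100L),
                    config$engine %||% list())
  stages <- config$stage %||% "analytic"
  artifacts <- list()

  provenance <- function(extra = list()) {
    c(list(package = "fretsphere",
           version = as.character(utils::packageVersion("fretsphere")),
           seed = seed, config = config), extra)
  }
  emit <- function(name, curve, value) {
    p <- file.path(out_dir, paste0(name, ".txt"))
    write_decay_file(curve, p, value = value)
    jsonlite::write_json(provenance(), file.path(out_dir,
                                                 paste0(name, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    p
  }

  for (st in stages) {
    if (st == "analytic") {
      lab <- config_section(config, "labeling", labeling_spec,
                            defaults = list(n_donors = 1, n_acceptors = 0))
      curve <- analytic_decay_curve(params, dist, lab$n_acceptors,
                                    k_max = hist_cfg$k_max,
                                    T_ns = hist_cfg$T_ns)
      artifacts$analytic <- curve
      artifacts$analytic_file <- emit("analytic_decay", curve, "intensity")
    } else if (st == "simulate") {
      lab <- config_section(config, "labeling", labeling_spec)
      curve <- simulate_decay(lab, dist, params, n_configs = eng$n_configs,
                              n_traj_per_config = eng$n_traj,
                              k_max = hist_cfg$k_max, T_ns = hist_cfg$T_ns)
      artifacts$simulated <- curve
      artifacts$counts_file <- emit("simulated_counts", curve, "counts")
      artifacts$survival_file <- emit("simulated_survival", curve, "survival")
    } else if (st == "generate") {
      lab <- config_section(config, "labeling", labeling_spec,
                            defaults = list(n_donors = 1, n_acceptors = 0))
      tc <- modifyList(list(total_counts = 1e6, background = 0, irf_fwhm = 0),
                       config$tcspc %||% list())
      model <- analytic_decay_curve(params, dist, lab$n_acceptors,
                                    k_max = hist_cfg$k_max,
                                    T_ns = hist_cfg$T_ns)
      curve <- generate_tcspc(model, tc$total_counts, tc$background,
                              tc$irf_fwhm)
      artifacts$tcspc <- curve
      artifacts$tcspc_file <- emit("tcspc_counts", curve, "counts")
    } else if (st == "fit") {
      fc <- config$fit %||% list()
      if (is.null(fc$input)) {
        abort("fit stage needs `fit$input` (a decay file path).",
              class = "fretsphere_config_error")
      }
      curve <- read_decay_file(fc$input)
      fit <- if (identical(fc$model, "monoexponential")) {
        fit_monoexponential(curve)
      } else {
        lab <- config_section(config, "labeling", labeling_spec,
                              defaults = list(n_donors = 1,
                                              n_acceptors = 100))
        fit_decay_model(curve, params, dist, lab$n_acceptors,
                        free = fc$free %||% c("n_acceptors", "mean_R",
                                              "amplitude"),
                        irf_fwhm = fc$irf_fwhm %||% 0)
      }
      artifacts$fit <- fit
      jsonlite::write_json(
        provenance(list(estimates = tidy(fit, conf.int = TRUE),
                        glance = glance(fit))),
        file.path(out_dir, "fit_report.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
      utils::write.table(
        data.frame(time_ns = fit$data$t, observed = fit$data$y,
                   fitted = fit$fitted,
                   residual = fit$data$y - fit$fitted),
        file.path(out_dir, "fit_residuals.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      artifacts$fit_file <- file.path(out_dir, "fit_report.json")
    } else if (st == "stats") {
      lab <- config_section(config, "labeling", labeling_spec)
      st_tbl <- migration_stats(lab, dist, params,
                                n_configs = eng$n_configs,
                                n_traj_per_config = eng$n_traj)
      artifacts$stats <- st_tbl
      jsonlite::write_json(provenance(list(migration_stats = st_tbl)),
                           file.path(out_dir, "migration_stats.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
      artifacts$stats_file <- file.path(out_dir, "migration_stats.json")
    } else {
      abort(sprintf("unknown stage '%s'.", st),
            class = "fretsphere_config_error")
    }
  }
  invisible(artifacts)
}
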