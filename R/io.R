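# Readers/writers for on-disk artifacts (breath tables, cohort directories,
# predictor equations, partitions) and the end-to-end pipeline driver.

breath_columns <- function() {
  c("t_s", "vo2_ml_min", "vco2_ml_min", "ve_l_min", "rf_per_min", "vt_l",
    "hr_bpm", "speed_kmh", "grade_pct")
}

#' Write a breath-by-breath CPET table
#'
#' CSV with '.' decimal separator, UTF-8, and leading '#' comment lines
#' carrying the recording metadata (`id`, `mass_kg`, `incremental_start_s`, ...).
#'
#' @param recording A `cpet_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_breath_table <- function(recording, path) {
  stopifnot(inherits(recording, "cpet_recording"))
  meta <- recording$meta
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# aeropower breath table v1", con)
  for (key in c("id", "sex", "age", "mass_kg", "height_cm",
                "warmup_s", "incremental_start_s")) {
    if (!is.null(meta[[key]])) {
      writeLines(sprintf("# %s: %s", key, format(meta[[key]], digits = 15)), con)
    }
  }
  cols <- intersect(breath_columns(), names(recording$breaths))
  utils::write.csv(recording$breaths[, cols], con, row.names = FALSE)
  invisible(path)
}

#' Read a breath-by-breath CPET table
#'
#' Validates that the required columns are present (error naming the missing
#' column) and that breath times are strictly increasing (error naming the
#' offending row).  '#' comment lines are parsed for metadata.
#'
#' @param path File written by [write_breath_table()] (or any CSV in the same
#'   dialect).
#' @return A `cpet_recording`.
#' @export
read_breath_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.+)$", ml))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  required <- c("t_s", "vo2_ml_min", "vco2_ml_min", "ve_l_min")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  cpet_recording(df, meta = meta)
}

#' Write a simulated cohort to a directory
#'
#' One breath CSV per subject, a `manifest.csv` (id, sex, age, mass_kg,
#' height_cm, pp_w, mp_w, fatigue_pct) and a `truth.json` with the generative
#' specification and true coefficients.
#'
#' @param cohort An `aeropower_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aeropower_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    write_breath_table(cohort$recordings[[id]],
                       file.path(dir, paste0("breaths_", id, ".csv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$planted_outcome <- NULL
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `recordings`, `manifest`, and `truth` (NULL if absent).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  files <- file.path(dir, paste0("breaths_", manifest$id, ".csv"))
  recordings <- lapply(files, read_breath_table)
  names(recordings) <- manifest$id
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                            simplifyVector = TRUE)
  else NULL
  list(recordings = recordings, manifest = manifest, truth = truth)
}

#' Write a predictor equation as JSON
#'
#' Lossless (full-precision) serialization of the equation schema:
#' `{outcome, intercept, terms: [{feature, coef}], scaler, provenance}`.
#'
#' @param equation A [predictor_equation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_equation <- function(equation, path) {
  stopifnot(inherits(equation, "predictor_equation"))
  obj <- list(
    outcome = equation$outcome,
    intercept = equation$intercept,
    terms = lapply(seq_along(equation$coefficients), function(i) {
      list(feature = names(equation$coefficients)[i],
           coef = unname(equation$coefficients[i]))
    })
  )
  if (!is.null(equation$scaler)) {
    obj$scaler <- lapply(stats::setNames(names(equation$scaler$mean),
                                         names(equation$scaler$mean)),
                         function(f) list(mean = unname(equation$scaler$mean[f]),
                                          sd = unname(equation$scaler$sd[f])))
  }
  if (!is.null(equation$provenance)) obj$provenance <- equation$provenance
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a predictor equation from JSON
#'
#' @param path File written by [write_equation()].
#' @return A [predictor_equation()].
#' @export
read_equation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  valid <- c("pp_w", "mp_w", "pp_w_per_kg", "mp_w_per_kg", "fatigue_pct")
  if (is.null(obj$outcome) || !obj$outcome %in% valid) {
    stop("schema error: unknown outcome tag: ",
         if (is.null(obj$outcome)) "(none)" else obj$outcome)
  }
  coefs <- vapply(obj$terms, function(t) t$coef, numeric(1))
  names(coefs) <- vapply(obj$terms, function(t) t$feature, character(1))
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- list(
      mean = vapply(obj$scaler, function(s) s$mean, numeric(1)),
      sd = vapply(obj$scaler, function(s) s$sd, numeric(1))
    )
  }
  predictor_equation(outcome = obj$outcome, intercept = obj$intercept,
                     coefficients = coefs, scaler = scaler,
                     provenance = obj$provenance)
}

#' Load one of the packaged published prediction equations
#'
#' The package ships re-encoded versions of the two published multiple-
#' regression equations for Wingate outcomes from standardized CPET features:
#' peak power (6 terms, intercept 638.4 W) and mean power (4 terms, intercept
#' 476.8 W).  Their inputs are standardized feature values, so evaluating them
#' at the all-zero vector returns the intercept.
#'
#' @param which `"pp"` (peak power) or `"mp"` (mean power).
#' @return A [predictor_equation()].
#' @export
#' @examples
#' eq <- published_equation("pp")
#' predict(eq, setNames(numeric(51), feature_registry()$name))
published_equation <- function(which = c("pp", "mp")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("equation_%s_published.json", which),
                      package = "aeropower", mustWork = TRUE)
  read_equation(path)
}

#' Write a network partition as JSON
#' @param partition A `network_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(list(groups = partition$groups, Q = partition$Q,
                            tree = partition$tree),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a feature network edge list as TSV
#' @param network A `feature_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param seed Master seed; every source of randomness derives from it.
#' @param n Cohort size.
#' @param gen A [generative_spec()] (default: a 6-feature peak-power-like
#'   planted signal with noise calibrated to a population R^2 of 0.9).
#' @param n_runs Stability runs per outer repeat.
#' @param n_outer Outer validation repeats.
#' @param fractions Train/test/validation split fractions.
#' @param termination Adjusted-R^2 stopping threshold.
#' @param stage Candidate stage filter.
#' @param window Feature-extraction smoothing window (breaths).
#' @param top_fraction Correlation-network edge fraction.
#' @param paper_faithful Standardize globally before splitting.
#' @param out_dir Optional output directory for the report bundle.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n = 88, gen = NULL, n_runs = 50, n_outer = 10,
                       fractions = c(train = 0.4, test = 0.3, validation = 0.3),
                       termination = 0.02, stage = "all", window = 10,
                       top_fraction = 0.30, paper_faithful = FALSE,
                       out_dir = NULL) {
  if (is.null(gen)) {
    gen <- generative_spec(
      signal_features = c("max_ve", "max_rf", "max_vo2", "max_slope_x_speed",
                          "slope_vco2_ve", "vo2max_over_slope_speed"),
      coefficients = c(170.3, -43.5, -77.5, 98.6, 39.3, 53),
      intercept = 638.4, noise_sd = "r2", target_r2 = 0.9, outcome = "pp_w")
  }
  structure(list(seed = seed, n = n, gen = gen, n_runs = n_runs,
                 n_outer = n_outer, fractions = fractions,
                 termination = termination, stage = stage, window = window,
                 top_fraction = top_fraction, paper_faithful = paper_faithful,
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(lapply(unclass(config), unclass), tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline: simulate, extract, train, cluster, report
#'
#' Executes the end-to-end flow on a simulated cohort: cohort simulation,
#' feature extraction (done inside the simulator), selection-and-validation
#' protocols for both peak and mean power, and modularity clustering of the
#' feature correlation network.  The report is deterministic for a given
#' configuration (no timestamps); timing is logged via `message()`.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_report` with `config_hash`, `cohort_summary`,
#'   `pp` and `mp` sections (aggregate metrics + consensus equation), and
#'   `clustering` (groups and Q).  If `config$out_dir` is set, writes
#'   `report.json`, `report.md`, the cohort, network edge list and partition
#'   there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  t_start <- Sys.time()
  stage_log <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[aeropower] %s ...", name))
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    message(sprintf("[aeropower] %s done (%.1f s)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  cohort <- stage_log("simulate", simulate_cohort(
    config$n, gen = config$gen, seed = config$seed, window = config$window))

  train_one <- function(outcome_col, label, seed_offset) {
    run_full_protocol(cohort$features, cohort$manifest[[outcome_col]],
                      stage = config$stage, n_outer = config$n_outer,
                      n_runs = config$n_runs, fractions = config$fractions,
                      termination = config$termination,
                      paper_faithful = config$paper_faithful,
                      outcome_label = label,
                      seed = config$seed + seed_offset)
  }
  pp <- stage_log("train PP", train_one("pp_w", "pp_w", 101L))
  mp <- stage_log("train MP", train_one("mp_w", "mp_w", 202L))

  clustering <- stage_log("cluster", {
    net <- build_network(correlation_matrix(cohort$features),
                         top_fraction = config$top_fraction)
    list(network = net, partition = cluster_network(net))
  })

  eq_section <- function(res) {
    eq <- res$last_equation
    list(aggregate = res$aggregate,
         consensus_frequency = as.list(res$consensus_frequency[
           res$consensus_frequency > 0]),
         equation = list(outcome = eq$outcome, intercept = eq$intercept,
                         terms = as.list(eq$coefficients)))
  }
  report <- structure(list(
    config_hash = hash,
    config = lapply(unclass(config)[setdiff(names(unclass(config)),
                                            c("gen", "out_dir"))],
                    identity),
    cohort_summary = list(
      n = nrow(cohort$manifest),
      n_female = sum(cohort$manifest$sex == "female"),
      n_male = sum(cohort$manifest$sex == "male"),
      dropped = cohort$truth$dropped,
      planted_outcome = cohort$truth$spec$outcome,
      planted_features = cohort$truth$signal_features,
      noise_sd = cohort$truth$noise_sd),
    pp = eq_section(pp),
    mp = eq_section(mp),
    clustering = list(groups = clustering$partition$groups,
                      Q = clustering$partition$Q,
                      n_edges = nrow(clustering$network$edges))
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_report_md(report), file.path(config$out_dir, "report.md"))
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    write_network(clustering$network, file.path(config$out_dir, "network.tsv"))
    write_partition(clustering$partition, file.path(config$out_dir, "partition.json"))
  }
  message(sprintf("[aeropower] pipeline complete (%.1f s total)",
                  as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  report
}

render_report_md <- function(report) {
  fmt_eq <- function(sec) {
    terms <- unlist(sec$equation$terms)
    paste0(sprintf("%.1f", sec$equation$intercept), " ",
           paste(sprintf("%+.1f * %s", terms, names(terms)), collapse = " "))
  }
  row <- function(label, sec) {
    a <- sec$aggregate
    sprintf("| %s | %s | %.2f (SD %.2f) | %.1f | %.1f +- %.1f |",
            label, fmt_eq(sec), a$spearman_mean, a$spearman_sd, a$rmse_mean,
            a$pct_err_mean, a$pct_err_sd)
  }
  c("# aeropower pipeline report",
    "",
    sprintf("config hash: `%s`", report$config_hash),
    sprintf("cohort: n = %d (%d female / %d male)",
            report$cohort_summary$n, report$cohort_summary$n_female,
            report$cohort_summary$n_male),
    "",
    "| Outcome | Equation | Spearman r (SD) | RMSE | Mean +- SD % error |",
    "|---|---|---|---|---|",
    row("Peak power (W)", report$pp),
    row("Mean power (W)", report$mp),
    "",
    sprintf("clustering: %d groups, Q = %.3f",
            length(report$clustering$groups), report$clustering$Q))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}
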