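#' Write an OTU table to TSV files
#'
#' Counts go to a TSV with OTU ids in the first column (`otu`) and one
#' column per sample; metadata to a TSV with columns
#' `sample,ecosystem,treatment,replicate,pair`; taxonomy (if present) to a
#' TSV with columns `otu,lineage`.
#'
#' @param table an [otu_table()].
#' @param counts_path,metadata_path,taxonomy_path output file paths;
#'   `taxonomy_path = NULL` skips taxonomy.
#' @return invisibly, the paths written.
#' @export
write_otu_table <- function(table, counts_path, metadata_path,
                            taxonomy_path = NULL) {
  stopifnot(inherits(table, "otu_table"))
  cnt <- data.frame(otu = colnames(table$counts),
                    t(table$counts), check.names = FALSE)
  utils::write.table(cnt, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(counts_path, metadata_path)
  if (!is.null(taxonomy_path) && !is.null(table$taxonomy)) {
    tx <- data.frame(otu = names(table$taxonomy),
                     lineage = unname(table$taxonomy))
    utils::write.table(tx, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, taxonomy_path)
  }
  invisible(paths)
}

#' Read an OTU table from TSV files
#'
#' Inverse of [write_otu_table()]. Validates ids and counts; a BIOM-style
#' `# Constructed from biom file` comment line at the top of the counts
#' file is tolerated. Parse errors name the offending line.
#'
#' @param counts_path TSV with `otu` first column, then sample columns.
#' @param metadata_path TSV with `sample,ecosystem,treatment,replicate,pair`.
#' @param taxonomy_path optional TSV with `otu,lineage`.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(counts_path, metadata_path,
                           taxonomy_path = NULL) {
  for (p in c(counts_path, metadata_path, taxonomy_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  first <- readLines(counts_path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  raw <- utils::read.delim(counts_path, check.names = FALSE, skip = skip,
                           colClasses = "character")
  if (names(raw)[1L] != "otu")
    stopf("malformed header in %s: first column must be 'otu'", counts_path)
  if (ncol(raw) < 2L) stopf("%s contains no sample columns", counts_path)
  if (anyDuplicated(names(raw)[-1L]))
    stopf("duplicate sample id in %s header", counts_path)
  if (anyDuplicated(raw$otu)) {
    dup <- raw$otu[duplicated(raw$otu)][1L]
    stopf("duplicate OTU id '%s' in %s (line %d)", dup, counts_path,
          which(raw$otu == dup)[2L] + 1L + skip)
  }
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(raw$otu, names(raw)[-1L]))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("invalid count '%s' at line %d, column '%s' of %s",
          raw[bad[1L, 1L], bad[1L, 2L] + 1L],
          bad[1L, 1L] + 1L + skip, colnames(num)[bad[1L, 2L]], counts_path)
  }
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
    if (!all(c("otu", "lineage") %in% names(tx)))
      stopf("malformed taxonomy header in %s", taxonomy_path)
    tax <- stats::setNames(tx$lineage, tx$otu)
  }
  otu_table(t(num), md, tax)
}

#' Write / read a sensor series as CSV
#'
#' Columns `timestamp,moisture,temperature,co2_ppmv` (timestamp in hours).
#'
#' @param series a [sensor_series()].
#' @param path CSV path.
#' @return `write_sensor_csv`: invisibly, the path; `read_sensor_csv`: a
#'   [sensor_series()].
#' @export
write_sensor_csv <- function(series, path) {
  stopifnot(inherits(series, "sensor_series"))
  d <- data.frame(timestamp = series$time_h,
                  moisture = series$moisture,
                  temperature = if ("temperature" %in% names(series))
                    series$temperature else NA,
                  co2_ppmv = series$co2)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path)
  need <- c("timestamp", "moisture", "co2_ppmv")
  if (!all(need %in% names(d)))
    stopf("malformed sensor CSV %s: needs columns %s", path,
          paste(need, collapse = ", "))
  temp <- if ("temperature" %in% names(d) && !all(is.na(d$temperature)))
    d$temperature
  sensor_series(d$timestamp, d$moisture, d$co2_ppmv, temp)
}

#' Write / read gradient fraction profiles as CSV
#'
#' Columns `unit,treatment,fraction,density_g_per_mL,copies`; one file may
#' carry several profiles.
#'
#' @param profiles a [fraction_profile()] or list of them.
#' @param path CSV path.
#' @return `write_fraction_csv`: invisibly, the path; `read_fraction_csv`:
#'   a named list of `fraction_profile` objects (one per unit/treatment).
#' @export
write_fraction_csv <- function(profiles, path) {
  if (inherits(profiles, "fraction_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(pr) {
    data.frame(unit = attr(pr, "unit"), treatment = attr(pr, "label"),
               fraction = pr$fraction, density_g_per_mL = pr$density,
               copies = pr$copies)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fraction_csv
#' @export
read_fraction_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path)
  need <- c("unit", "treatment", "fraction", "density_g_per_mL", "copies")
  if (!all(need %in% names(d)))
    stopf("malformed fraction CSV %s: needs columns %s", path,
          paste(need, collapse = ", "))
  out <- list()
  for (key in unique(paste(d$unit, d$treatment, sep = "/"))) {
    sub <- d[paste(d$unit, d$treatment, sep = "/") == key, ]
    sub <- sub[order(sub$fraction), ]
    out[[key]] <- fraction_profile(sub$fraction, sub$density_g_per_mL,
                                   sub$copies, label = sub$treatment[1L],
                                   unit = sub$unit[1L])
  }
  out
}

#' Write / read gas time courses as CSV
#'
#' Columns `unit,ecosystem,treatment,species,time_h,conc_ppmv`; vial
#' constants travel separately (arguments of `read_gas_csv`).
#'
#' @param timecourses a [gas_timecourse()] or list of them.
#' @param path CSV path.
#' @param soil_g,headspace_mL,temp_C,pressure_atm vial constants attached
#'   on read.
#' @return `write_gas_csv`: invisibly, the path; `read_gas_csv`: a list of
#'   `gas_timecourse` objects.
#' @export
write_gas_csv <- function(timecourses, path) {
  if (inherits(timecourses, "gas_timecourse"))
    timecourses <- list(timecourses)
  rows <- do.call(rbind, lapply(timecourses, function(tc) {
    data.frame(unit = tc$unit, ecosystem = tc$ecosystem,
               treatment = tc$treatment, species = tc$species,
               time_h = tc$time_h, conc_ppmv = tc$conc_ppmv)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gas_csv
#' @export
read_gas_csv <- function(path, soil_g = 3, headspace_mL = 37.7,
                         temp_C = 25, pressure_atm = 1) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path)
  need <- c("unit", "ecosystem", "treatment", "species", "time_h",
            "conc_ppmv")
  if (!all(need %in% names(d)))
    stopf("malformed gas CSV %s: needs columns %s", path,
          paste(need, collapse = ", "))
  out <- list()
  for (key in unique(paste(d$unit, d$species, sep = "/"))) {
    sub <- d[paste(d$unit, d$species, sep = "/") == key, ]
    sub <- sub[order(sub$time_h), ]
    out[[key]] <- gas_timecourse(sub$time_h, sub$conc_ppmv,
                                 unit = sub$unit[1L],
                                 ecosystem = sub$ecosystem[1L],
                                 treatment = sub$treatment[1L],
                                 species = sub$species[1L],
                                 soil_g = soil_g,
                                 headspace_mL = headspace_mL,
                                 temp_C = temp_C,
                                 pressure_atm = pressure_atm)
  }
  out
}

#' Run the full synthetic-to-report pipeline
#'
#' Generates a synthetic experiment and runs every analysis stage —
#' `simulate` (paired OTU tables, gradient profiles, sensor series, gas
#' time courses), `sip` (incorporation verdicts), `pulse` (lagged CO2
#' regression), `gas` (net production + ANOVA), `community` (rarefaction,
#' Bray-Curtis, PERMANOVA) and `rare` (rare-responder reports) — writing
#' every intermediate as TSV/CSV/JSON under `out_dir` together with a
#' manifest recording package version, seed and parameters. Reruns with the
#' same config give identical outputs.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; per-stage seeds derive from it.
#' @param seed_bank,sensor,gradient,gas parameter objects; defaults are the
#'   package defaults reseeded from `seed`.
#' @param inputs optional named list of pre-existing input files
#'   (`counts`, `metadata`, optionally `taxonomy`) to analyse instead of
#'   simulating the OTU table; missing files abort with an error naming
#'   the path.
#' @param n_perm PERMANOVA permutations.
#' @param threshold dominance threshold for the rare-responder report.
#' @return invisibly, a list of the stage results (also serialized under
#'   `out_dir`).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         seed_bank = NULL, sensor = NULL,
                         gradient = NULL, gas = NULL,
                         inputs = NULL, n_perm = 999, threshold = 0.01) {
  seed <- check_count(seed, "seed", lower = 0L)
  if (!is.null(inputs)) {
    for (p in unlist(inputs))
      if (!file.exists(p)) stopf("input file not found: %s", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, msg, ...)
    cat(sprintf("%s\t%s\t%s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, sprintf(msg, ...)),
        file = log_path, append = TRUE)

  seed_bank <- seed_bank %||% seed_bank_params(seed = seed)
  sensor <- sensor %||% sensor_sim_params(seed = seed + 1L)
  gradient <- gradient %||% gradient_sim_params(seed = seed + 2L)
  gas <- gas %||% gas_sim_params(seed = seed + 3L)

  # --- simulate ---------------------------------------------------------
  logf("simulate", "start (seed %d)", seed)
  sim <- if (is.null(inputs)) generate_paired_otu_tables(seed_bank) else
    list(table = read_otu_table(inputs$counts, inputs$metadata,
                                inputs$taxonomy),
         truth = NULL)
  write_otu_table(sim$table,
                  file.path(out_dir, "otu_counts.tsv"),
                  file.path(out_dir, "sample_metadata.tsv"),
                  file.path(out_dir, "taxonomy.tsv"))
  if (!is.null(sim$truth))
    jsonlite::write_json(sim$truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = FALSE)
  sens <- generate_sensor_series(sensor)
  write_sensor_csv(sens$series, file.path(out_dir, "sensor.csv"))
  prof_dry <- generate_fraction_profiles(gradient, labeled = FALSE)
  prof_rew <- generate_fraction_profiles(gradient, labeled = TRUE)
  write_fraction_csv(list(prof_dry, prof_rew),
                     file.path(out_dir, "fractions.csv"))
  gas_design <- generate_design(seed_bank$n_ecosystems, 2L,
                                seed_bank$n_replicates)
  tcs <- generate_gas_timecourses(gas, gas_design)
  write_gas_csv(tcs, file.path(out_dir, "gas.csv"))
  logf("simulate", "end: %d samples, %d taxa", nrow(sim$table$counts),
       ncol(sim$table$counts))

  # --- sip --------------------------------------------------------------
  logf("sip", "start")
  verdict <- classify_incorporation(prof_dry, prof_rew)
  jsonlite::write_json(
    list(incorporation = verdict$incorporation,
         shift_min = verdict$shift_min, shift_max = verdict$shift_max,
         unlabeled_fractions = verdict$unlabeled_window$indices,
         labeled_fractions = verdict$labeled_window$indices),
    file.path(out_dir, "sip_verdict.json"), auto_unbox = TRUE, digits = NA)
  logf("sip", "end: incorporation=%s", verdict$incorporation)

  # --- pulse ------------------------------------------------------------
  logf("pulse", "start")
  agg <- aggregate_series(sens$series, 12)
  fit <- fit_pulse_model(agg)
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         se = as.list(fit$se), r_squared = fit$r_squared,
         r_squared_quasi = fit$r_squared_quasi, rho = fit$rho,
         n_obs = fit$n_obs),
    file.path(out_dir, "pulse_fit.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(predict(fit, agg),
                     file.path(out_dir, "pulse_predicted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("pulse", "end: R2=%.3f", fit$r_squared)

  # --- gas --------------------------------------------------------------
  logf("gas", "start")
  nps <- lapply(tcs, net_production)
  np_df <- do.call(rbind, lapply(nps, function(np)
    data.frame(unit = np$unit, ecosystem = np$ecosystem,
               treatment = np$treatment, species = np$species,
               value = np$value)))
  utils::write.table(np_df, file.path(out_dir, "net_production.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  aov_tab <- two_way_anova(np_df$value, np_df$ecosystem, np_df$treatment)
  jsonlite::write_json(aov_tab, file.path(out_dir, "gas_anova.json"),
                       dataframe = "rows", digits = NA)
  logf("gas", "end")

  # --- community --------------------------------------------------------
  logf("community", "start")
  rar <- rarefy(sim$table, seed = seed + 10L)
  d <- bray_curtis_matrix(rar)
  utils::write.table(d, file.path(out_dir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE)
  pmv <- permanova(d, rar$metadata$ecosystem, rar$metadata$treatment,
                   n_perm = n_perm, seed = seed + 11L)
  jsonlite::write_json(pmv, file.path(out_dir, "permanova.json"),
                       dataframe = "rows", digits = NA)
  logf("community", "end")

  # --- rare -------------------------------------------------------------
  logf("rare", "start")
  pairs <- pairs_from_table(rar, seed = seed + 12L)
  reports <- lapply(pairs, rare_responder_report, threshold = threshold)
  rep_df <- do.call(rbind, lapply(reports, function(r)
    data.frame(pair = r$pair, ecosystem = r$ecosystem,
               shared = length(r$shared), dry_only = length(r$dry_only),
               rewet_only = length(r$rewet_only),
               rare_otu_fraction = r$rare_otu_fraction,
               rare_seq_fraction = r$rare_seq_fraction,
               singleton_doubleton_fraction =
                 r$singleton_doubleton_fraction,
               n_dominant = nrow(r$dominant_responders))))
  utils::write.table(rep_df, file.path(out_dir, "rare_responders.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tax_mat <- NULL
  if (!is.null(sim$table$taxonomy)) {
    tax_mat <- taxonomy_recovery_matrix(pairs, sim$table$taxonomy,
                                        level = 1L)
    utils::write.table(tax_mat, file.path(out_dir, "taxonomy_recovery.tsv"),
                       sep = "\t", quote = FALSE)
  }
  logf("rare", "end")

  manifest <- list(
    package = "rewetSIP",
    version = as.character(utils::packageVersion("rewetSIP")),
    seed = seed,
    stages = c("simulate", "sip", "pulse", "gas", "community", "rare"),
    n_perm = n_perm, threshold = threshold,
    parameters = list(seed_bank = unclass(seed_bank),
                      sensor = unclass(sensor),
                      gradient = unclass(gradient),
                      gas = unclass(gas)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, verdict = verdict, pulse = fit,
                 net_production = np_df, anova = aov_tab,
                 permanova = pmv, reports = reports,
                 taxonomy_recovery = tax_mat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
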