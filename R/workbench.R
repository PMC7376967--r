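# Orchestration: configuration, end-to-end field and statistics pipelines,
# and the commanded-stimulus waveform check.

#' Read a run configuration (YAML or JSON)
#'
#' Recognized fields (all optional): `voxel_size_um`, `tissue_table`
#' (CSV path), `montages` (list of `{name, current_A, frequency_hz,
#' contact_diameter_mm, electrodes: [{ap, ml, role}]}`), `targets`,
#' `solver: {tol, maxiter}`, `safety_threshold`, `seed`.
#'
#' @param path YAML (or JSON) file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  if (!is.null(cfg$safety_threshold) && cfg$safety_threshold <= 0)
    stop("safety_threshold must be > 0")
  structure(cfg, class = "run_config")
}

config_montages <- function(cfg) {
  if (is.null(cfg$montages)) return(list(bilateral_montage()))
  lapply(cfg$montages, function(m) {
    els <- lapply(m$electrodes, function(e)
      electrode(e$ap, e$ml, e$contact_diameter_mm %||% 1.5, e$role))
    montage(els, m$current_A %||% 1e-4, m$frequency_hz %||% 40,
            m$name %||% "montage")
  })
}

#' Run the full field-simulation pipeline
#'
#' Builds the phantom, places and solves every configured montage, and
#' writes an artifact bundle to `out_dir`: `phi`/`magE`/`magJ` NIfTI
#' volumes (first-ranked montage), an ROI statistics CSV, a montage-ranking
#' CSV, a safety-report JSON, and a run log carrying the package version and
#' a hash of the configuration.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory.
#' @return List with `phantom`, `evaluation`, `safety`, `files` (the
#'   manifest), invisibly printed to the log.
#' @export
run_field_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))

  tt <- if (!is.null(config$tissue_table)) read_tissue_table(config$tissue_table)
        else default_tissue_table()
  spec <- stage("phantom", phantom_spec(
    voxel_size_um = config$voxel_size_um %||% 100, tissue_table = tt))
  phantom <- stage("phantom", build_phantom(spec))
  montages <- stage("montage", config_montages(config))
  tol <- config$solver$tol %||% 1e-8
  maxiter <- config$solver$maxiter %||% 50000
  targets <- unlist(config$targets) %||% c("hippocampus", "svz")

  ev <- stage("solve", compare_montages(phantom, montages, targets,
                                        tol = tol, maxiter = maxiter,
                                        keep_fields = TRUE))
  best <- ev$table$montage[ev$table$rank == 1]
  best_mont <- montages[[which(vapply(montages, `[[`, "", "name") == best)[1]]]
  sol <- stage("solve", solve_montage(phantom, best_mont,
                                      tol = tol, maxiter = maxiter))

  files <- character(0)
  files <- c(files, stage("write", write_field_maps_nifti(
    sol$potential, sol$fields, out_dir)))

  roi_all <- do.call(rbind, lapply(names(ev$roi), function(nm) {
    df <- as.data.frame(ev$roi[[nm]])
    df$montage <- nm
    df$coverage_score <- ev$table$coverage_score_V_per_m[ev$table$montage == nm]
    df$rank <- ev$table$rank[ev$table$montage == nm]
    df
  }))
  roi_csv <- file.path(out_dir, "roi_statistics.csv")
  utils::write.csv(roi_all, roi_csv, row.names = FALSE)
  rank_csv <- file.path(out_dir, "montage_ranking.csv")
  utils::write.csv(ev$table, rank_csv, row.names = FALSE)
  files <- c(files, roi_csv, rank_csv)

  safety <- stage("safety", safety_check(sol$fields, phantom,
                                         config$safety_threshold %||% 20))
  safety_json <- file.path(out_dir, "safety_report.json")
  jsonlite::write_json(unclass(safety)[c("max_parenchymal_magJ", "threshold",
                                         "passed", "n_voxels_considered")],
                       safety_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, safety_json)

  cfg_hash <- digest_config(config)
  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("iacsim %s", as.character(utils::packageVersion("iacsim"))),
    sprintf("config hash: %s", cfg_hash),
    sprintf("voxel size: %g um; unknowns solved per montage at tol %g",
            phantom$voxel_size_um, tol),
    sprintf("best montage: %s", best),
    sprintf("max parenchymal |J|: %.6g A/m^2 (threshold %g): %s",
            safety$max_parenchymal_magJ, safety$threshold,
            if (safety$passed) "PASS" else "FAIL")), log_path)
  files <- c(files, log_path)

  invisible(list(phantom = phantom, evaluation = ev, safety = safety,
                 best_montage = best, files = files))
}

digest_config <- function(config) {
  # stable content hash without extra dependencies: sum of serialized bytes
  raw <- serialize(config[order(names(unclass(config)))], NULL, version = 2)
  sprintf("%08x-%d", sum(as.integer(raw)) %% 0xFFFFFFF, length(raw))
}

#' Run the cell-count statistics pipeline
#'
#' For view-level input the counts are aggregated per animal first; the
#' pipeline then computes group summaries, one one-way ANOVA plus Tukey HSD
#' per region x marker, and the iACS-vs-control fold changes. With
#' `input = "fixture"` the embedded printed group summaries are analysed via
#' [reproduce_published_table()] and Tukey tests run directly on the summaries.
#'
#' @param input Path to a counts CSV (view-level columns
#'   `animal_id,group,region,marker,section_index,view_index,count` or
#'   aggregated `animal_id,group,region,marker,value`), or the string
#'   `"fixture"`.
#' @param out_dir Optional directory; when given, tidy `anova.csv`,
#'   `tukey.csv` and `fold_changes.csv` are written.
#' @param convention View-aggregation convention, see [aggregate_views()].
#' @return List with data.frames `anova`, `tukey`, `fold_changes`.
#' @export
run_stats_pipeline <- function(input, out_dir = NULL,
                               convention = c("sum", "mean")) {
  convention <- match.arg(convention)
  if (identical(input, "fixture")) {
    fx <- neurogenesis_summaries()
    pt <- reproduce_published_table()
    anova_df <- pt$anova
    fc_df <- pt$fold_changes
    tk <- lapply(split(fx, list(fx$region, fx$marker)), function(s) {
      t <- tukey_hsd(s)
      cbind(region = s$region[1], marker = s$marker[1], as.data.frame(t))
    })
    tukey_df <- do.call(rbind, tk)
    rownames(tukey_df) <- NULL
  } else {
    df <- utils::read.csv(input, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("schema error: input CSV has no rows")
    if (all(c("section_index", "view_index", "count") %in% names(df))) {
      df <- aggregate_views(df, convention)
    } else if (!all(c("animal_id", "group", "region", "marker", "value")
                    %in% names(df))) {
      stop("schema error: need view-level or aggregated count columns; got ",
           paste(names(df), collapse = ", "))
    }
    if (any(df$value < 0)) {
      bad <- which(df$value < 0)
      stop("schema error: negative values in rows ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    cells <- split(df, list(df$region, df$marker), drop = TRUE)
    anova_df <- do.call(rbind, lapply(cells, function(s) {
      a <- anova_from_counts(split(s$value, s$group))
      data.frame(region = s$region[1], marker = s$marker[1], F = a$F,
                 df_between = a$df_between, df_within = a$df_within,
                 p = a$p)
    }))
    tukey_df <- do.call(rbind, lapply(cells, function(s) {
      t <- tukey_hsd(split(s$value, s$group))
      cbind(region = s$region[1], marker = s$marker[1], as.data.frame(t))
    }))
    fc_df <- do.call(rbind, lapply(cells, function(s) {
      g <- split(s$value, s$group)
      if (!all(c("5xFAD", "5xFAD+iACS") %in% names(g))) return(NULL)
      fc <- fold_change(mean(g[["5xFAD+iACS"]]), mean(g[["5xFAD"]]))
      data.frame(region = s$region[1], marker = s$marker[1],
                 ratio = fc$ratio, ratio_rounded = fc$ratio_rounded)
    }))
    rownames(anova_df) <- rownames(tukey_df) <- NULL
    if (!is.null(fc_df)) rownames(fc_df) <- NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(anova_df, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(tukey_df, file.path(out_dir, "tukey.csv"),
                     row.names = FALSE)
    utils::write.csv(fc_df, file.path(out_dir, "fold_changes.csv"),
                     row.names = FALSE)
  }
  list(anova = anova_df, tukey = tukey_df, fold_changes = fc_df)
}

#' Generate the commanded stimulation waveform
#'
#' Pure zero-mean sine (no DC component, matching a stimulator validated to
#' exclude DC leak).
#'
#' @param frequency Hz (> 0).
#' @param amplitude Peak current, A.
#' @param sampling_rate Hz; must exceed twice the frequency (Nyquist).
#' @param duration Seconds (> 0).
#' @return Object of class `waveform`: `samples` (A), `sampling_rate`,
#'   `nominal_frequency`, `amplitude`.
#' @export
#' @examples
#' w <- generate_stim_waveform(40, 1e-4, 1000, 1)
#' psd_peak(w)
generate_stim_waveform <- function(frequency, amplitude = 1e-4,
                                   sampling_rate = 1000, duration = 10) {
  if (frequency <= 0) stop("frequency must be > 0")
  stopifnot(duration > 0, amplitude > 0)
  if (sampling_rate <= 2 * frequency)
    stop("Nyquist violation: sampling_rate must exceed 2 * frequency")
  n <- round(sampling_rate * duration)
  t <- (seq_len(n) - 1) / sampling_rate
  structure(list(samples = amplitude * sin(2 * pi * frequency * t),
                 sampling_rate = sampling_rate,
                 nominal_frequency = frequency, amplitude = amplitude),
            class = "waveform")
}

#' Dominant frequency of a waveform
#'
#' Periodogram (squared FFT magnitude over the full record) peak location;
#' a constant record peaks at 0 Hz.
#'
#' @param w A `waveform`.
#' @return Frequency of the PSD maximum, Hz.
#' @export
psd_peak <- function(w) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  if (n < 2 * w$sampling_rate / w$nominal_frequency)
    stop("record too short: need at least 2 cycles")
  p <- Mod(stats::fft(w$samples))^2
  half <- seq_len(floor(n / 2) + 1)
  freqs <- (half - 1) * w$sampling_rate / n
  freqs[which.max(p[half])]
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %g Hz, amplitude %g A, %d samples at %g Hz\n",
              x$nominal_frequency, x$amplitude, length(x$samples),
              x$sampling_rate))
  invisible(x)
}

#' @export
plot.waveform <- function(x, n_cycles = 3, ...) {
  n <- min(length(x$samples),
           ceiling(n_cycles * x$sampling_rate / x$nominal_frequency))
  t <- (seq_len(n) - 1) / x$sampling_rate
  graphics::plot(t, x$samples[seq_len(n)], type = "l",
                 xlab = "time (s)", ylab = "current (A)", ...)
  invisible(x)
}
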