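#' Pipeline configuration
#'
#' Validated orchestration config. Top-level sections: `samples` (a list;
#' each entry has `id`, `group`, and either `preset` + `seed` or `path`,
#' optional `blood_glucose_mg_dl`, `notes`), `channels` (`islet`, `nerve`,
#' `ganglion`), `segmentation` (`largest_islet_diameter_um`,
#' `min_object_volume_um3`, `th_filter`), `spatial` (`distance_cutoff_um`,
#' `ganglion_volume_range_um3`, `ganglion_sphericity_min`), `stats`
#' (`metrics`, `alpha`), `output` (`dir`, `qc_projection`), `noise`,
#' `log_level`. Unknown keys anywhere are rejected before any computation.
#'
#' @param x a file path to a YAML config, or a named list.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  schema <- list(
    samples = c("id", "group", "preset", "seed", "path", "config",
                "blood_glucose_mg_dl", "notes"),
    channels = c("islet", "nerve", "ganglion"),
    segmentation = c("largest_islet_diameter_um", "min_object_volume_um3",
                     "th_filter"),
    spatial = c("distance_cutoff_um", "ganglion_volume_range_um3",
                "ganglion_sphericity_min"),
    stats = c("metrics", "alpha"),
    output = c("dir", "qc_projection"),
    noise = NULL, log_level = NULL)
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in c("channels", "segmentation", "spatial", "stats", "output")) {
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$samples) || length(cfg$samples) == 0L)
    stop("config needs at least one sample")
  if (is.null(cfg$channels) || is.null(cfg$channels$islet))
    stop("config needs a channel map with at least an islet channel")
  for (s in cfg$samples) {
    bad <- setdiff(names(s), schema$samples)
    if (length(bad))
      stop("unknown sample key(s): ", paste(bad, collapse = ", "))
    if (is.null(s$id) || is.null(s$group))
      stop("every sample needs `id` and `group`")
    if (is.null(s$preset) && is.null(s$path))
      stop(sprintf("sample '%s' needs `preset` or `path`", s$id))
  }
  defaults <- list(
    segmentation = list(largest_islet_diameter_um = 250,
                        min_object_volume_um3 = 0, th_filter = FALSE),
    spatial = list(distance_cutoff_um = 1.6,
                   ganglion_volume_range_um3 = c(20000, 400000),
                   ganglion_sphericity_min = 0.4),
    stats = list(metrics = c("beta_volume_percent", "islets_per_mm3",
                             "pct_innervated",
                             "endocrine_nerve_density_percent",
                             "exocrine_nerve_density_percent"),
                 alpha = 0.05),
    output = list(dir = NULL, qc_projection = FALSE),
    noise = TRUE, log_level = "info")
  for (nm in names(defaults))
    cfg[[nm]] <- if (is.list(defaults[[nm]]))
      modifyList(defaults[[nm]], as.list(cfg[[nm]])) else
        if (is.null(cfg[[nm]])) defaults[[nm]] else cfg[[nm]]
  structure(cfg, class = "pipeline_config")
}

analyze_sample <- function(grid, cfg, sample_id = "sample") {
  ch <- cfg$channels
  islets <- segment_islets(grid, channel = ch$islet,
                           largest_islet_diameter_um =
                             cfg$segmentation$largest_islet_diameter_um,
                           min_object_volume_um3 =
                             cfg$segmentation$min_object_volume_um3)
  nerves <- if (!is.null(ch$nerve) && ch$nerve %in% names(grid$channels))
    segment_nerves(grid, nerve_channel = ch$nerve) else NULL
  if (!is.null(nerves) && isTRUE(cfg$segmentation$th_filter)) {
    insulin_mask <- get_channel(grid, ch$islet) >
      otsu_threshold(get_channel(grid, ch$islet))
    nerves <- filter_th_beta_cells(nerves, object_mask(islets), insulin_mask)
  }
  nerve_mask <- if (!is.null(nerves)) object_mask(nerves) else
    array(FALSE, dim(grid))
  records <- islet_nerve_distances(islets, nerve_mask,
                                   distance_cutoff_um =
                                     cfg$spatial$distance_cutoff_um)
  tissue_mask <- if (!is.null(grid$region_mask)) grid$region_mask > 0L
                 else array(TRUE, dim(grid))
  insulin <- get_channel(grid, ch$islet)
  summary <- region_summary(records, nerve_mask, tissue_mask,
                            grid$voxel_size_um,
                            region_mask = grid$region_mask,
                            intensity_channel = ch$islet,
                            nerve_intensity_channel = ch$nerve,
                            tissue_mean_intensity =
                              mean(insulin[tissue_mask]))
  ganglia <- NULL
  gang <- NULL
  if (!is.null(ch$ganglion) && ch$ganglion %in% names(grid$channels)) {
    ganglia <- detect_ganglia(grid, channel = ch$ganglion,
                              volume_range_um3 =
                                cfg$spatial$ganglion_volume_range_um3,
                              sphericity_min =
                                cfg$spatial$ganglion_sphericity_min)
    gang <- ganglion_metrics(ganglia, object_mask(islets), tissue_mask)
  }
  innerv <- classify_innervation(records,
                                 cfg$spatial$distance_cutoff_um)
  comparison <- if (nrow(records)) innervated_comparison(records) else NULL
  list(sample_id = sample_id, islets = islets, nerves = nerves,
       records = records, summary = summary, innervation = innerv,
       comparison = comparison, ganglia = ganglia,
       ganglion_metrics = gang)
}

#' Run the full simulate/segment/quantify/stats pipeline
#'
#' Executes every stage per sample (synthesizing phantoms for preset
#' samples, reading volumes for path samples), aggregates per-sample
#' headline metrics, runs normality-gated group comparisons for each
#' configured metric when two or more groups are present, correlates
#' metrics with blood glucose when provided, and (when an output directory
#' is configured) writes all tables, QC maximum projections and a run log.
#'
#' @param config a `pipeline_config`, a path to one, or a named list.
#' @return a `study_result` with `samples` (per-sample detail),
#'   `per_sample` (metric table), `group_stats`, `correlations`, `config`.
#' @export
run_study <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  samples <- list()
  rows <- list()
  for (s in config$samples) {
    grid <- if (!is.null(s$preset)) {
      pcfg <- phantom_preset(s$preset)
      if (!is.null(s$config)) # per-sample generative overrides (e.g. size)
        pcfg <- phantom_config_override(pcfg, s$config)
      ph <- generate_phantom(pcfg, seed = if (is.null(s$seed)) 1L else s$seed,
                             noise = config$noise)
      ph$grid
    } else read_volume(s$path)
    res <- tryCatch(analyze_sample(grid, config, s$id),
                    error = function(e) stop(sprintf(
                      "stage failure in sample '%s': %s", s$id,
                      conditionMessage(e)), call. = FALSE))
    tot <- res$summary[res$summary$scope == "total", ]
    rows[[s$id]] <- data.frame(
      sample_id = s$id, group = s$group,
      blood_glucose_mg_dl = if (is.null(s$blood_glucose_mg_dl)) NA_real_
                            else s$blood_glucose_mg_dl,
      beta_volume_percent = tot$beta_volume_percent,
      islets_per_mm3 = tot$islets_per_mm3,
      median_islet_volume_um3 = tot$median_islet_volume_um3,
      pct_innervated = tot$pct_innervated,
      endocrine_nerve_density_percent = tot$endocrine_nerve_density_percent,
      exocrine_nerve_density_percent = tot$exocrine_nerve_density_percent,
      innervated_volume_share_pct = tot$innervated_volume_share_pct,
      ganglia_per_mm3 = if (!is.null(res$ganglion_metrics))
        res$ganglion_metrics$density_per_mm3 else NA_real_)
    if (isTRUE(config$output$qc_projection) && !is.null(config$output$dir)) {
      dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
      mip <- max_projection(grid, config$channels$islet)
      tiff::writeTIFF(mip / max(mip, 1e-9),
                      file.path(config$output$dir,
                                sprintf("qc_mip_%s.tif", s$id)))
    }
    samples[[s$id]] <- res
  }
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL

  group_stats <- list()
  groups <- unique(per_sample$group)
  if (length(groups) >= 2L) {
    counts <- table(per_sample$group)
    if (all(counts >= 2L)) {
      for (m in config$stats$metrics) {
        if (!m %in% names(per_sample)) next
        if (all(is.na(per_sample[[m]]))) next
        group_stats[[m]] <- tryCatch(
          group_compare(per_sample, m, "group", alpha = config$stats$alpha),
          error = function(e) NULL)
      }
    }
  }
  correlations <- list()
  if (any(is.finite(per_sample$blood_glucose_mg_dl)) &&
      sum(is.finite(per_sample$blood_glucose_mg_dl)) >= 3L) {
    for (m in c("beta_volume_percent", "islets_per_mm3",
                "endocrine_nerve_density_percent")) {
      ok <- is.finite(per_sample$blood_glucose_mg_dl) &
            is.finite(per_sample[[m]])
      if (sum(ok) >= 3L && sd(per_sample[[m]][ok]) > 0)
        correlations[[m]] <- correlate(per_sample$blood_glucose_mg_dl[ok],
                                       per_sample[[m]][ok])
    }
  }
  result <- structure(list(samples = samples, per_sample = per_sample,
                           group_stats = group_stats,
                           correlations = correlations, config = config),
                      class = "study_result")
  if (!is.null(config$output$dir)) write_results(result, config$output$dir)
  result
}

#' Write study tables, stats and a manifest
#'
#' Per-islet, per-ganglion and per-sample tables as RFC-4180 CSV (UTF-8,
#' `.` decimal, header row), group statistics as structured JSON, and a
#' manifest listing every file. Re-running on identical input overwrites
#' the files with identical bytes.
#'
#' @param study_result a `study_result` (or a named list of data.frames).
#' @param out_dir output directory (created if absent).
#' @return character vector of written file names (the manifest content),
#'   invisibly.
#' @export
write_results <- function(study_result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop(sprintf("output directory '%s' is not writable", out_dir))
  files <- character(0)
  emit <- function(df, name) {
    if (is.null(df) || nrow(df) == 0L) return(invisible(NULL))
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n")
    files <<- c(files, name)
  }
  if (inherits(study_result, "study_result")) {
    tag <- function(df, id) if (is.null(df) || nrow(df) == 0L) NULL
                            else cbind(sample_id = id, df)
    recs <- lapply(study_result$samples, function(s)
      tag(s$records, s$sample_id))
    recs <- recs[!vapply(recs, is.null, TRUE)]
    if (length(recs)) emit(do.call(rbind, recs), "islet_records.csv")
    gang <- lapply(study_result$samples, function(s)
      if (!is.null(s$ganglion_metrics))
        tag(s$ganglion_metrics$records, s$sample_id))
    gang <- gang[!vapply(gang, is.null, TRUE)]
    if (length(gang)) emit(do.call(rbind, gang), "ganglion_records.csv")
    sums <- lapply(study_result$samples, function(s)
      cbind(sample_id = s$sample_id, s$summary))
    emit(do.call(rbind, sums), "region_summaries.csv")
    emit(study_result$per_sample, "per_sample_metrics.csv")
    if (length(study_result$group_stats) > 0L) {
      stats_out <- lapply(study_result$group_stats, function(gs)
        list(metric = gs$metric, test = gs$test, gate = gs$gate,
             statistic = gs$statistic, p_value = gs$p_value,
             significant = gs$significant,
             per_group = gs$per_group, pairwise = gs$pairwise))
      jsonlite::write_json(stats_out,
                           file.path(out_dir, "group_stats.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows", na = "null")
      files <- c(files, "group_stats.json")
    }
  } else if (is.list(study_result)) {
    for (nm in names(study_result))
      emit(study_result[[nm]], paste0(nm, ".csv"))
  }
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(data.frame(file = files), manifest, row.names = FALSE,
            eol = "\n")
  invisible(files)
}

#' One-page study report
#'
#' Markdown summary mirroring the headline figure-panel metrics: per-sample
#' volumetrics, innervation partition, innervated/non-innervated
#' comparison, ganglion metrics and the group statistics. Every number is
#' read from the already-computed tables; nothing is recomputed here.
#'
#' @param study_result a `study_result`.
#' @return character vector of markdown lines, invisibly; also printed.
#' @export
report <- function(study_result) {
  if (!inherits(study_result, "study_result") ||
      length(study_result$samples) == 0L)
    stop("empty study result")
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  lines <- c("# Islet innervation study report", "")
  ps <- study_result$per_sample
  lines <- c(lines, "## Per-sample metrics", "",
             paste("|", paste(names(ps), collapse = " | "), "|"),
             paste("|", paste(rep("---", ncol(ps)), collapse = " | "), "|"))
  for (i in seq_len(nrow(ps)))
    lines <- c(lines, paste("|", paste(vapply(ps[i, ], function(v)
      if (is.numeric(v)) fmt(v, 3) else as.character(v), ""),
      collapse = " | "), "|"))
  lines <- c(lines, "")
  for (s in study_result$samples) {
    tot <- s$summary[s$summary$scope == "total", ]
    lines <- c(lines, sprintf("## Sample %s", s$sample_id),
      sprintf("- beta cell volume: %s%% of tissue; %s islets (%s /mm^3)",
              fmt(tot$beta_volume_percent), tot$n_islets,
              fmt(tot$islets_per_mm3, 1)),
      sprintf("- volume bins (<1k / 1k-50k / 50k-500k / >500k um^3): %s%%",
              paste(fmt(c(tot$volume_bin_pct_1, tot$volume_bin_pct_2,
                          tot$volume_bin_pct_3, tot$volume_bin_pct_4), 2),
                    collapse = " / ")),
      sprintf("- innervated islets: %s%%; innervated share of islet volume: %s%%",
              fmt(tot$pct_innervated), fmt(tot$innervated_volume_share_pct)),
      sprintf("- nerve density endocrine / exocrine: %s%% / %s%%",
              fmt(tot$endocrine_nerve_density_percent, 4),
              fmt(tot$exocrine_nerve_density_percent, 4)))
    if (!is.null(s$ganglion_metrics))
      lines <- c(lines, sprintf(
        "- ganglia: %d (%s /mm^3), mean volume %s um^3, mean islet distance %s um",
        nrow(s$ganglion_metrics$records),
        fmt(s$ganglion_metrics$density_per_mm3, 1),
        fmt(mean(s$ganglion_metrics$records$volume_um3), 0),
        fmt(mean(s$ganglion_metrics$records$distance_to_nearest_islet_um), 1)))
    lines <- c(lines, "")
  }
  if (length(study_result$group_stats)) {
    lines <- c(lines, "## Group comparisons", "")
    for (gs in study_result$group_stats)
      lines <- c(lines, sprintf("- %s: %s (%s gate), statistic %.4g, p = %.4g%s",
                                gs$metric, gs$test, gs$gate, gs$statistic,
                                gs$p_value,
                                if (gs$significant) " (significant)" else ""))
    lines <- c(lines, "")
  }
  if (length(study_result$correlations)) {
    lines <- c(lines, "## Blood-glucose correlations", "")
    for (m in names(study_result$correlations)) {
      co <- study_result$correlations[[m]]
      lines <- c(lines, sprintf("- glucose vs %s: %s = %.3f, p = %.4g", m,
                                if (co$method == "pearson") "r" else "rho",
                                co$estimate, co$p_value))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
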