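#' Run the full suitability pipeline from a structured config
#'
#' Executes simulate -> prep -> fit -> evaluate -> project -> mess ->
#' ensemble -> report for a set of (virtual) species over an ensemble of
#' climate scenarios and periods, writing every artefact (rasters,
#' occurrence CSVs, model files, report CSVs) plus a YAML run manifest
#' recording the config snapshot, per-stage seeds, input digests and output
#' paths. Every random stage derives its own seed from the config, so a
#' rerun from the same config is bit-reproducible.
#'
#' The config is a YAML file (or an equivalent named list) with blocks:
#' \preformatted{
#' out_dir: runs/demo
#' seed: 1
#' simulate: {width: 80, height: 80, n_vars: 4, smoothness: 5,
#'            land_fraction: 0.9, n_species: 3, n_presence: 300,
#'            n_scenarios: 6, periods: [2030, 2050, 2070],
#'            noise_scale: 0.25, novelty_target: 0.2}
#' prep:     {min_date: 1950-01-01, buffer_km: 200, max_background: 10000,
#'            r_max: 0.8}
#' fit:      {kinds: [linear, quadratic, product], reg_multiplier: 1,
#'            c0: 1.0, tol: 1.0e-7, max_iter: 2000}
#' evaluate: {k: 5}
#' project:  {scale: logistic, threshold: p10}
#' ensemble: {min_agree: 4}
#' }
#' Missing keys fall back to the defaults above (a missing threshold rule
#' defaults to the 10th-percentile training presence rule with a logged
#' notice).
#'
#' @param config path to a YAML config file, or a named list.
#' @param quiet suppress progress logging.
#' @return the run manifest (named list), invisibly; also written to
#'   `<out_dir>/manifest.yaml`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("`config` must be a YAML path or a named list",
                          call. = FALSE)
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %-9s %s",
                                format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
  need <- function(block, key, default) {
    val <- (cfg[[block]] %||% list())[[key]]
    if (is.null(val)) {
      if (identical(key, "threshold")) {
        log_line(block, sprintf(
          "no threshold rule in config; defaulting to p10 training presence"))
      }
      default
    } else {
      val
    }
  }
  out_dir <- cfg$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed0 <- as.integer(cfg$seed %||% 1L)
  stage_seed <- function(k) (seed0 * 1000L + k) %% .Machine$integer.max

  # --- simulate ------------------------------------------------------
  width <- need("simulate", "width", 80)
  height <- need("simulate", "height", 80)
  n_vars <- need("simulate", "n_vars", 4)
  n_species <- need("simulate", "n_species", 3)
  n_presence <- need("simulate", "n_presence", 300)
  n_scen <- need("simulate", "n_scenarios", 6)
  periods <- as.character(need("simulate", "periods",
                               c("2030", "2050", "2070")))
  log_line("simulate", sprintf(
    "%dx%d grid, %d vars, %d species, %d scenarios x %d periods",
    width, height, n_vars, n_species, n_scen, length(periods)))
  baseline <- make_climate(width, height, n_vars = n_vars,
                           smoothness = need("simulate", "smoothness", 5),
                           land_fraction = need("simulate", "land_fraction",
                                                0.9),
                           seed = stage_seed(1L))
  family <- make_scenarios(baseline, n = n_scen,
                           noise_scale = need("simulate", "noise_scale",
                                              0.25),
                           novelty_target = need("simulate",
                                                 "novelty_target", 0.2),
                           periods = periods, seed = stage_seed(2L))
  spp <- lapply(seq_len(n_species), function(k) {
    make_virtual_species(baseline,
                         species = sprintf("Virtualis sp%02d", k),
                         seed = stage_seed(10L + k))
  })
  raster_dir <- file.path(out_dir, "rasters")
  write_stack(baseline, raster_dir, prefix = "baseline_")
  occ_paths <- character(n_species)
  for (k in seq_len(n_species)) {
    recs <- sample_presences(spp[[k]], n_presence,
                             seed = stage_seed(20L + k))
    occ_paths[k] <- file.path(out_dir,
                              sprintf("occurrences_sp%02d.csv", k))
    write_occurrences(recs, occ_paths[k])
  }
  truth <- data.frame(
    species = vapply(spp, `[[`, character(1L), "species"),
    do.call(rbind, lapply(spp, function(v) {
      c(stats::setNames(v$linear, paste0("linear_", names(v$linear))),
        stats::setNames(v$quadratic,
                        paste0("quadratic_", names(v$quadratic))))
    }))
  )
  utils::write.csv(truth, file.path(out_dir, "truth_weights.csv"),
                   row.names = FALSE)

  # --- per-species modelling -----------------------------------------
  grid <- stack_ref_grid(baseline)
  land <- land_cells(grid)
  scale <- need("project", "scale", "logistic")
  need("project", "threshold", "p10")   # logs the default notice
  min_agree <- need("ensemble", "min_agree", floor(n_scen / 2) + 1)
  cons_u <- stats::setNames(
    rep(list(vector("list", n_species)), length(periods)), periods)
  cons_m <- cons_u
  cv_rows <- list()
  for (k in seq_len(n_species)) {
    sp_name <- spp[[k]]$species
    log_line("prep", sp_name)
    recs <- read_occurrences(occ_paths[k], species = sp_name)
    filt <- filter_records(recs, sp_name, grid,
                           min_date = need("prep", "min_date", "1950-01-01"))
    presence <- thin_to_cells(filt)
    background <- sample_background(
      presence, grid, buffer_km = need("prep", "buffer_km", 200),
      max_n = need("prep", "max_background", 10000),
      seed = stage_seed(30L + k))
    vars <- screen_collinearity(baseline, names(baseline$layers),
                                background$background_cells,
                                r_max = need("prep", "r_max", 0.8))
    log_line("fit", sprintf("%s: %d presences, %d background, vars %s",
                            sp_name, presence$m, background$achieved_n,
                            paste(vars, collapse = ",")))
    spec <- build_features(baseline, vars,
                           kinds = need("fit", "kinds",
                                        c("linear", "quadratic", "product")),
                           background_cells = background$background_cells)
    model <- maxent_fit(presence, background, spec, baseline,
                        reg_multiplier = need("fit", "reg_multiplier", 1),
                        c0 = need("fit", "c0", 1.0),
                        tol = need("fit", "tol", 1e-7),
                        max_iter = need("fit", "max_iter", 2000))
    write_model(model, file.path(out_dir,
                                 sprintf("model_sp%02d.txt", k)))
    cv <- cross_validate(presence, background, spec, baseline,
                         k = need("evaluate", "k", 5),
                         seed = stage_seed(40L + k))
    cv_rows[[k]] <- data.frame(species = sp_name, mean_auc = cv$mean_auc,
                               sd_auc = cv$sd_auc)
    thr <- threshold_p10(training_presence_scores(model, scale),
                         scale = scale)
    ref_cells <- sort(unique(c(presence$presence_cells,
                               background$background_cells)))
    ref_values <- stack_values(baseline, ref_cells, vars)
    base_bin <- project_binary(model, baseline, thr)
    base_mess <- mess(ref_values, baseline, vars)
    for (p in periods) {
      log_line("project", sprintf("%s / %s", sp_name, p))
      bins_u <- list(); bins_m <- list()
      for (s in seq_len(n_scen)) {
        stack_s <- family$scenarios[[p]][[s]]
        bin <- project_binary(model, stack_s, thr)
        ms <- mess(ref_values, stack_s, vars)
        bins_u[[s]] <- bin
        bins_m[[s]] <- mask_novel(bin, ms)
      }
      cons_u[[p]][[k]] <- consensus(bins_u, min_agree = min_agree)
      cons_m[[p]][[k]] <- consensus(bins_m, min_agree = min_agree)
    }
    # baseline-period maps enter as 1-scenario consensus
    cons_u[["baseline"]][[k]] <- as_consensus(base_bin)
    cons_m[["baseline"]][[k]] <- as_consensus(mask_novel(base_bin,
                                                         base_mess))
  }
  utils::write.csv(do.call(rbind, cv_rows),
                   file.path(out_dir, "cv_report.csv"), row.names = FALSE)

  # --- ensemble report -----------------------------------------------
  summaries <- list()
  hotspots <- list()
  summary_paths <- character(0)
  for (p in c("baseline", periods)) {
    hot_u <- stack_species(cons_u[[p]])
    hot_m <- stack_species(cons_m[[p]])
    hotspots[[p]] <- list(unmasked = hot_u, masked = hot_m)
    sm <- area_summary(hot_u, hot_m, land_mask = grid)
    pth <- file.path(out_dir, sprintf("area_summary_%s.csv", p))
    write_area_summary(sm, pth)
    summaries[[p]] <- sm
    summary_paths <- c(summary_paths, pth)
    log_line("report", sprintf(
      "%s: %.1f%% of land suitable for >= 1 species (%.1f%% masked)", p,
      100 - sm$pct_unmasked[1L], 100 - sm$pct_masked[1L]))
  }

  manifest <- list(
    tool = "flyclim",
    version = as.character(utils::packageVersion("flyclim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed0,
    config = cfg,
    inputs = as.list(tools::md5sum(occ_paths)),
    outputs = list(
      rasters = raster_dir,
      occurrences = occ_paths,
      truth = file.path(out_dir, "truth_weights.csv"),
      cv_report = file.path(out_dir, "cv_report.csv"),
      area_summaries = summary_paths
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(c(manifest, list(
    summaries = summaries,
    consensus = list(unmasked = cons_u, masked = cons_m),
    hotspots = hotspots
  )))
}
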