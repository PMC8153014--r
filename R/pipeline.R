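#' Pipeline configuration
#'
#' Bundles the scene (or input paths), composite spec, combinations to run,
#' seeds and forest parameters for [run_pipeline()]. Unknown keys in `...`
#' are rejected so configuration typos fail loudly.
#'
#' @param scene a [scene_config()] for a simulated run.
#' @param composite a [composite_spec()].
#' @param tags dataset combinations to classify.
#' @param cloud_threshold cloud-score masking threshold.
#' @param ntree,mtry random forest parameters.
#' @param seed master seed for selection/training stages.
#' @param run_rfe logical; run recursive feature elimination per tag.
#' @param n_polygons_per_class,n_points_per_class reference sampling sizes.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param ... rejected; present to catch misspelled arguments.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(),
                            composite = composite_spec(),
                            tags = c("S2", "S2+", "S1", "S1+", "S2+S1+",
                                     "S2+S1+DEM"),
                            cloud_threshold = 0.5,
                            ntree = 100, mtry = 2, seed = 1,
                            run_rfe = TRUE,
                            n_polygons_per_class = 2,
                            n_points_per_class = 50,
                            out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(names(extra), collapse = ", ")), call. = FALSE)
  }
  lapply(tags, combination_features)  # validates tags
  structure(list(scene = scene, composite = composite, tags = tags,
                 cloud_threshold = cloud_threshold, ntree = ntree,
                 mtry = mtry, seed = as.integer(seed), run_rfe = run_rfe,
                 n_polygons_per_class = n_polygons_per_class,
                 n_points_per_class = n_points_per_class,
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  core <- unclass(config)
  core$out_dir <- NULL  # the hash identifies the computation, not its sink
  saveRDS(core, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full classification experiment on a scene
#'
#' Executes simulate -> cloud mask -> percentile composites -> feature
#' assembly per combination -> (optional) recursive feature elimination ->
#' random forest training -> map prediction -> majority filter -> accuracy
#' assessment, then pairwise McNemar comparisons and the UA/PA improvement
#' analysis against the best-OA combination. With an `out_dir`, maps,
#' reports, selection curves and a run manifest are written.
#'
#' @param config a [pipeline_config()].
#' @param scene optionally, a pre-simulated `labeled_scene` (the config's
#'   scene is then ignored).
#' @return a list: `results` (per tag: selection, model, map, accuracy),
#'   `comparison` (McNemar table and `comparison_report`), `area` (for the
#'   last/fullest tag), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), scene = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    out
  }
  if (is.null(scene)) {
    scene <- stage("simulate", simulate_scene(
      config$scene, config$n_polygons_per_class, config$n_points_per_class))
  }
  optical_masked <- stage("cloud_mask",
                          mask_clouds(scene$optical, config$cloud_threshold))
  optical_comp <- stage("composite_optical",
                        percentile_range_composite(optical_masked,
                                                   config$composite))
  radar_comp <- stage("composite_radar",
                      percentile_range_composite(scene$radar, config$composite))
  results <- list()
  for (tag in config$tags) {
    feats <- stage(paste0("features_", tag),
                   assemble_combination(tag, optical = optical_comp,
                                        radar = radar_comp,
                                        radar_series = scene$radar,
                                        dem = scene$dem))
    table <- stage(paste0("extract_", tag),
                   standardize(extract_training_pixels(feats, scene$reference)))
    sel <- NULL
    if (config$run_rfe && ncol(table$x) >= 2) {
      sel <- stage(paste0("select_", tag),
                   rfe_select(table, config$ntree, config$mtry,
                              seed = config$seed))
      table_sel <- table
      table_sel$x <- table$x[, sel$selected, drop = FALSE]
    } else {
      table_sel <- table
    }
    model <- stage(paste0("train_", tag),
                   train_rf(table_sel, config$ntree, config$mtry,
                            seed = config$seed))
    map <- stage(paste0("classify_", tag), predict_map(model, feats))
    map <- stage(paste0("filter_", tag), majority_filter(map, 3))
    acc <- stage(paste0("evaluate_", tag), confusion(map, scene$reference))
    imp <- per_class_importance(model, table_sel)
    results[[tag]] <- list(selection = sel, model = model, map = map,
                           accuracy = acc, importance = imp,
                           n_training = nrow(table$x),
                           dropped = table$dropped)
  }
  comparison <- NULL
  if (length(results) >= 2) {
    tags <- names(results)
    pairs <- t(utils::combn(tags, 2))
    mc <- data.frame(first = pairs[, 1], second = pairs[, 2],
                     f12 = NA_real_, f21 = NA_real_,
                     statistic = NA_real_, p_value = NA_real_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mc))) {
      dc <- discordant_counts(results[[mc$first[i]]]$map,
                              results[[mc$second[i]]]$map, scene$reference)
      mc$f12[i] <- dc$f12; mc$f21[i] <- dc$f21
      if (dc$f12 + dc$f21 > 0) {
        m <- mcnemar(dc$f12, dc$f21)
        mc$statistic[i] <- m$statistic; mc$p_value[i] <- m$p_value
      }
    }
    oas <- vapply(results, function(r) r$accuracy$oa, 0)
    best <- names(which.max(oas))
    improvement <- improvement_analysis(
      results[[best]]$accuracy,
      results[setdiff(tags, best)] |> lapply(function(r) r$accuracy))
    comparison <- list(mcnemar = mc, best = best, oa = oas,
                       improvement = improvement)
  }
  area <- area_report(results[[length(results)]]$map)
  manifest <- list(tool = "peatstack",
                   version = as.character(utils::packageVersion("peatstack")),
                   config_hash = config_digest(config),
                   seed = config$seed,
                   timings = timings,
                   checksums = list())
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    outs <- character(0)
    for (tag in names(results)) {
      safe <- gsub("\\+", "p", tag)
      mp <- file.path(config$out_dir, paste0("map_", safe, ".tif"))
      write_raster(results[[tag]]$map, mp)
      rp <- file.path(config$out_dir, paste0("accuracy_", safe, ".json"))
      a <- results[[tag]]$accuracy
      jsonlite::write_json(list(oa = a$oa, ua = as.list(a$ua),
                                pa = as.list(a$pa),
                                f_score = as.list(a$f_score),
                                matrix = a$matrix), rp, digits = NA,
                           auto_unbox = TRUE, na = "null")
      outs <- c(outs, mp, sidecar_path(mp), rp)
      if (!is.null(results[[tag]]$selection)) {
        sp <- file.path(config$out_dir, paste0("selection_", safe, ".json"))
        s <- results[[tag]]$selection
        jsonlite::write_json(list(curve = s$curve, optimal_size = s$optimal_size,
                                  selected = s$selected, seed = s$seed),
                             sp, digits = NA, auto_unbox = TRUE)
        utils::write.csv(s$curve,
                         file.path(config$out_dir, paste0("curve_", safe, ".csv")),
                         row.names = FALSE)
        outs <- c(outs, sp)
      }
      ip <- file.path(config$out_dir, paste0("importance_", safe, ".csv"))
      utils::write.csv(
        data.frame(feature = rownames(results[[tag]]$importance$per_class),
                   overall = results[[tag]]$importance$overall,
                   results[[tag]]$importance$per_class, check.names = FALSE),
        ip, row.names = FALSE)
      outs <- c(outs, ip)
    }
    if (!is.null(comparison)) {
      cp <- file.path(config$out_dir, "comparison.json")
      jsonlite::write_json(
        list(mcnemar = comparison$mcnemar, best = comparison$best,
             oa = as.list(comparison$oa),
             improvement = list(
               n_positive = comparison$improvement$n_positive,
               n_negative = comparison$improvement$n_negative,
               n_zero = comparison$improvement$n_zero)),
        cp, digits = NA, auto_unbox = TRUE, na = "null")
      outs <- c(outs, cp)
    }
    manifest$checksums <- as.list(tools::md5sum(sort(outs)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest$wall_clock_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(results = results, comparison = comparison, area = area,
       manifest = manifest)
}
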