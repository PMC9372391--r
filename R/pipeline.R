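#' Default pipeline configuration
#'
#' A plain hierarchical list of every pipeline parameter. All values can
#' be overridden by a YAML file ([read_run_config()]) or directly.
#'
#' @param out_dir Output directory of the run.
#' @param seed Run seed; all stage seeds derive from it.
#' @return Named list of configuration blocks.
#' @export
default_run_config <- function(out_dir = "uavagb_run", seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("SP", "FP", "TP"),
    scene = list(),              # overrides passed to scene_config()
    glcm = list(levels = 32L, distance = 1L),
    fvc = list(method = "dpm", confidence = 0.98),
    vi_v_mode = "pixel",
    selection = list(methods = c("rrelieff", "rf_gini", "rf_oob"),
                     top_n = 10L),
    split = list(ratio = 2 / 3),
    log_level = "info"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_run_config()]; everything
#' else keeps its default.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]])
    } else user[[k]]
  }
  base
}

log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[uavagb] ", ...)
}

scene_paths <- function(config, stage) {
  d <- file.path(config$out_dir, "scenes")
  list(dir = d,
       cube = file.path(d, paste0(stage, "_reflectance.tif")),
       dsm = file.path(d, paste0(stage, "_dsm.tif")),
       dem = file.path(d, paste0(stage, "_dem.tif")),
       layout = file.path(d, paste0(stage, "_layout.csv")),
       truth = file.path(d, paste0(stage, "_truth.csv")),
       endmembers = file.path(d, paste0(stage, "_endmembers.csv")))
}

require_upstream <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing ", path, "; run `", producer, "` first", call. = FALSE)
  }
  path
}

#' Pipeline commands
#'
#' Five idempotent stages of the simulate - extract - select - fit -
#' report workflow, each reading its inputs from and writing its outputs
#' under `config$out_dir`. Given an identical configuration (including
#' the seed) every command reproduces its outputs exactly; a missing
#' upstream artifact raises an error naming the stage to run first.
#'
#' @param config Configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @return Invisibly, the paths written (or, for `cmd_report`, the merged
#'   summary data frame).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(config = default_run_config()) {
  written <- character(0)
  for (stage in config$stages) {
    sc_args <- c(list(seed = derive_seed(config$seed,
                                         paste0("scene-", stage)),
                      stage = stage), config$scene)
    scene <- generate_scene(do.call(scene_config, sc_args))
    p <- scene_paths(config, stage)
    dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
    write_cube(scene$cube, p$cube)
    write_raster(scene$dsm, p$dsm)
    write_raster(scene$dem, p$dem)
    write_plot_table(scene$layout, p$layout)
    utils::write.csv(scene$truth$plots, p$truth, row.names = FALSE)
    write_endmember_library(scene$endmembers, p$endmembers)
    log_msg(config, "simulate: wrote stage ", stage, " scene to ", p$dir)
    written <- c(written, p$cube, p$dsm, p$dem, p$layout, p$truth,
                 p$endmembers)
  }
  invisible(written)
}

# Rebuild in-memory scenes from the files cmd_simulate wrote.
load_scene_files <- function(config) {
  lapply(config$stages, function(stage) {
    p <- scene_paths(config, stage)
    require_upstream(p$cube, "simulate")
    layout <- read_plot_table(p$layout)
    structure(list(cube = read_cube(p$cube),
                   dsm = read_raster(p$dsm), dem = read_raster(p$dem),
                   truth = NULL, layout = layout,
                   endmembers = read_endmember_library(p$endmembers),
                   config = do.call(scene_config,
                                    c(list(seed = config$seed,
                                           stage = stage),
                                      config$scene))),
              class = "uav_scene")
  })
}

#' @rdname pipeline
#' @export
cmd_extract <- function(config = default_run_config()) {
  scenes <- load_scene_files(config)
  ft <- extract_features(scenes,
                         glcm_levels = config$glcm$levels,
                         glcm_distance = config$glcm$distance,
                         fvc_method = config$fvc$method,
                         dpm_confidence = config$fvc$confidence,
                         vi_v_mode = config$vi_v_mode,
                         seed = config$seed)
  path <- file.path(config$out_dir, "features.csv")
  write_feature_table(ft, path)
  jsonlite::write_json(attr(ft, "texture_source"),
                       file.path(config$out_dir, "texture_source.json"),
                       auto_unbox = TRUE)
  log_msg(config, "extract: ", sum(lengths(attr(ft, "dims"))),
          " feature columns for ", nrow(ft), " samples")
  invisible(path)
}

load_feature_file <- function(config) {
  path <- require_upstream(file.path(config$out_dir, "features.csv"),
                           "extract")
  ft <- read_feature_table(path)
  ts <- jsonlite::read_json(file.path(config$out_dir,
                                      "texture_source.json"),
                            simplifyVector = TRUE)
  attr(ft, "dims") <- feature_dimensions(ts$band, ts$direction)
  ft
}

#' @rdname pipeline
#' @export
cmd_select <- function(config = default_run_config()) {
  ft <- load_feature_file(config)
  written <- character(0)
  for (method in config$selection$methods) {
    ranking <- selection_ranking(method, ft, seed = config$seed)
    path <- file.path(config$out_dir,
                      paste0("ranking_", method, ".csv"))
    utils::write.csv(ranking, path, row.names = FALSE)
    log_msg(config, "select: ", method, " top feature = ",
            select_top(ranking, 1L))
    written <- c(written, path)
  }
  invisible(written)
}

#' @rdname pipeline
#' @export
cmd_fit <- function(config = default_run_config()) {
  ft <- load_feature_file(config)
  methods_tab2 <- c("none", sub("-", "_", config$selection$methods))
  tab2 <- run_experiment(ft, selections = methods_tab2,
                         regressions = c("plsr", "rfr"),
                         ratio = config$split$ratio,
                         top_n = config$selection$top_n,
                         seed = config$seed)
  tab3 <- run_experiment(ft, selections = "rf_oob",
                         regressions = c("plsr", "rfr"),
                         combinations = enumerate_combinations(),
                         ratio = config$split$ratio,
                         top_n = config$selection$top_n,
                         seed = config$seed)
  write_report(tab2, file.path(config$out_dir, "report_selection"))
  write_report(tab3, file.path(config$out_dir, "report_combinations"))
  utils::write.csv(attr(tab2, "predictions"),
                   file.path(config$out_dir, "predictions_selection.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(tab3, "predictions"),
                   file.path(config$out_dir,
                             "predictions_combinations.csv"),
                   row.names = FALSE)
  log_msg(config, "fit: wrote selection and combination reports")
  invisible(file.path(config$out_dir,
                      c("report_selection.csv",
                        "report_combinations.csv")))
}

#' @rdname pipeline
#' @export
cmd_report <- function(config = default_run_config()) {
  p2 <- require_upstream(file.path(config$out_dir,
                                   "report_selection.csv"), "fit")
  p3 <- require_upstream(file.path(config$out_dir,
                                   "report_combinations.csv"), "fit")
  tab2 <- utils::read.csv(p2, stringsAsFactors = FALSE)
  tab3 <- utils::read.csv(p3, stringsAsFactors = FALSE)
  summary <- rbind(cbind(experiment = "selection_methods", tab2),
                   cbind(experiment = "dimension_combinations", tab3))
  path <- file.path(config$out_dir, "summary")
  write_report(summary, path)
  log_msg(config, "report: merged summary at ", path, ".csv")
  invisible(summary)
}
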