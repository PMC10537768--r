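# Full pipeline: filter -> cluster -> select -> align -> trim -> downsample
# -> features (-> predict), with a per-stage report.

#' Pipeline configuration
#'
#' Bundles and validates every stage parameter before any stage runs.
#'
#' @param sf_k,sf_sigma statistical filter, see [filter_params()].
#' @param eps,min_pts DBSCAN, see [dbscan_params()].
#' @param cluster_min_size,floor_margin pig-cluster selection, see
#'   [select_pig_cluster()].
#' @param voxel_size voxel cube side, m.
#' @param alpha outline probe radius (`NULL` = automatic).
#' @param sag_min minimum split-candidate concavity depth, m.
#' @param head_direction `"+x"` or `"-x"`.
#' @param raster_h,raster_w back raster size.
#' @param cnn a [cnn_config()].
#' @param scene a [scene_params()] used by simulation commands.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sf_k = 30L, sf_sigma = 2, eps = 0.02,
                            min_pts = 10L, cluster_min_size = 100L,
                            floor_margin = 0.1, voxel_size = 0.005,
                            alpha = NULL, sag_min = 0.03,
                            head_direction = "+x", raster_h = 64L,
                            raster_w = 64L, cnn = cnn_config(),
                            scene = scene_params()) {
  filt <- filter_params(sf_k, sf_sigma)          # validates
  db <- dbscan_params(eps, min_pts)
  if (!is.finite(voxel_size) || voxel_size <= 0)
    pigback_error("voxel_size must be positive", "pigback_param_error")
  if (!is.finite(sag_min) || sag_min <= 0)
    pigback_error("sag_min must be positive", "pigback_param_error")
  if (!head_direction %in% c("+x", "-x"))
    pigback_error("head_direction must be '+x' or '-x'",
                  "pigback_param_error")
  if (!is.null(alpha) && (!is.finite(alpha) || alpha <= 0))
    pigback_error("alpha must be positive", "pigback_param_error")
  cluster_min_size <- as.integer(cluster_min_size)
  if (is.na(cluster_min_size) || cluster_min_size < 1L)
    pigback_error("cluster_min_size must be >= 1", "pigback_param_error")
  raster_h <- as.integer(raster_h); raster_w <- as.integer(raster_w)
  if (any(is.na(c(raster_h, raster_w))) || raster_h < 4L || raster_w < 4L)
    pigback_error("raster dimensions must be at least 4", "pigback_param_error")
  stopifnot(inherits(cnn, "cnn_config"), inherits(scene, "scene_params"))
  structure(list(filter = filt, dbscan = db,
                 cluster_min_size = cluster_min_size,
                 floor_margin = floor_margin, voxel_size = voxel_size,
                 alpha = alpha, sag_min = sag_min,
                 head_direction = head_direction, raster_h = raster_h,
                 raster_w = raster_w, cnn = cnn, scene = scene),
            class = "pipeline_config")
}

#' Run the full segmentation and feature pipeline on one cloud
#'
#' Stages in order: statistical filter, DBSCAN, pig-cluster selection,
#' horizontal alignment, head/tail trimming, voxel downsampling, back
#' feature extraction, and (when a trained model is supplied) raster
#' prediction of the weight. Any stage failure aborts with the stage name.
#'
#' @param cloud input [point_cloud()].
#' @param config a [pipeline_config()].
#' @param model optional trained `pigback_cnn` or `pigback_rbf` model.
#' @return list with `features` (a [back_features()]), `weight` (kg or
#'   `NULL`), `report` (per-stage data frame), `raster`, and the trimmed
#'   downsampled `cloud`.
#' @export
run_pipeline <- function(cloud, config = pipeline_config(), model = NULL) {
  stopifnot(inherits(cloud, "point_cloud"),
            inherits(config, "pipeline_config"))
  report <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer(), params = character(),
                       stringsAsFactors = FALSE)
  stage <- function(name, n_in, expr, params = "") {
    res <- tryCatch(expr, error = function(e) {
      pigback_error(paste0("stage ", name, ": ", conditionMessage(e)),
                    "pigback_stage_error")
    })
    report[nrow(report) + 1L, ] <<- list(
      name, n_in,
      if (inherits(res, "point_cloud")) n_points(res) else n_in,
      params)
    res
  }

  filtered <- stage("statistical_filter", n_points(cloud),
                    statistical_filter(cloud, config$filter)$kept,
                    sprintf("k=%d sigma=%g", config$filter$k,
                            config$filter$sigma))
  labeling <- stage("dbscan", n_points(filtered),
                    dbscan(filtered, config$dbscan),
                    sprintf("eps=%g min_pts=%d", config$dbscan$eps,
                            config$dbscan$min_pts))
  pig <- stage("select_pig_cluster", n_points(filtered),
               select_pig_cluster(filtered, labeling,
                                  config$cluster_min_size,
                                  config$floor_margin),
               sprintf("min_size=%d floor_margin=%g",
                       config$cluster_min_size, config$floor_margin))
  aligned <- stage("align_horizontal", n_points(pig),
                   align_horizontal(pig)$cloud)
  trimmed <- stage("split_head_tail", n_points(aligned),
                   suppressWarnings(
                     split_head_tail(aligned, config$sag_min,
                                     config$head_direction,
                                     config$alpha))$cloud,
                   sprintf("sag_min=%g head=%s", config$sag_min,
                           config$head_direction))
  down <- stage("voxel_downsample", n_points(trimmed),
                voxel_downsample(trimmed, config$voxel_size),
                sprintf("r=%g", config$voxel_size))
  features <- stage("extract_back_features", n_points(down),
                    extract_back_features(down, config$alpha))
  raster <- rasterize_back(down, config$raster_h, config$raster_w)
  weight <- NULL
  if (!is.null(model)) {
    rec <- list(list(raster = raster, features = features))
    weight <- stage("predict", n_points(down), predict(model, rec))
  }
  list(features = features, weight = weight, report = report,
       raster = raster, cloud = down)
}
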