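# Core data types and PLY/CSV input-output.

#' Point labels recognised by the synthetic scenes and scoring helpers
#' @export
POINT_LABELS <- c("pig_torso", "pig_head", "pig_tail", "floor",
                  "outlier_large", "outlier_small", "unknown")

PIG_LABELS <- c("pig_torso", "pig_head", "pig_tail")

#' Construct a point cloud
#'
#' A point cloud is an unordered set of 3D coordinates in metres, with `z` the
#' height above the floor plane (increasing upward; the overhead depth camera
#' is conceptually at z = 2.5 m). Point order carries no meaning; every
#' downstream operation is order-invariant up to documented tie-break rules.
#'
#' @param points numeric matrix with three columns (x, y, z), metres.
#' @param labels optional character vector, one tag per point, drawn from
#'   [POINT_LABELS].
#' @return an object of class `point_cloud` with elements `points` and
#'   `labels` (possibly `NULL`).
#' @export
point_cloud <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (length(points) == 0L) {
    points <- matrix(numeric(0), ncol = 3L)
  }
  if (ncol(points) != 3L)
    stop("`points` must have exactly three columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("all coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(points))
      stop("`labels` must have exactly one tag per point")
    bad <- setdiff(unique(labels), POINT_LABELS)
    if (length(bad))
      stop("unknown point labels: ", paste(bad, collapse = ", "))
  }
  structure(list(points = points, labels = labels), class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()]
#' @return integer count
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s>\n", n_points(x),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

# subset a cloud, carrying labels through
cloud_subset <- function(cloud, keep) {
  point_cloud(cloud$points[keep, , drop = FALSE],
              if (is.null(cloud$labels)) NULL else cloud$labels[keep])
}

pigback_error <- function(msg, class) {
  stop(structure(class = c(class, "pigback_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# ---------------------------------------------------------------------------
# PLY

.ply_sizes <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw, type, n) {
  switch(type,
    char = , int8 = readBin(raw, "integer", n = n, size = 1L, signed = TRUE),
    uchar = , uint8 = readBin(raw, "integer", n = n, size = 1L, signed = FALSE),
    short = , int16 = readBin(raw, "integer", n = n, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(raw, "integer", n = n, size = 2L,
                                signed = FALSE, endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(raw, "integer", n = n, size = 4L, endian = "little"),
    float = , float32 = readBin(raw, "numeric", n = n, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(raw, "numeric", n = n, size = 8L,
                                 endian = "little"),
    stop("unsupported PLY property type: ", type))
}

#' Read a point cloud from a PLY file
#'
#' Supports ASCII and binary little-endian PLY with a `vertex` element holding
#' scalar `x`, `y`, `z` properties (float32 or float64; other per-vertex
#' properties such as colours are ignored). Big-endian files are rejected.
#'
#' @param path path to a PLY file.
#' @return a [point_cloud()] without labels, one point per vertex record.
#' @export
read_ply <- function(path) {
  if (!file.exists(path))
    pigback_error(paste0("cannot read PLY file: ", path), "pigback_io_error")
  con <- file(path, "rb")
  on.exit(close(con))

  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      pigback_error("PLY header has no end_header line", "pigback_format_error")
    line <- sub("\r$", "", line)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 10000L)
      pigback_error("PLY header too long or malformed", "pigback_format_error")
  }
  if (!grepl("^ply\\s*$", header[1]))
    pigback_error("not a PLY file (missing 'ply' magic)", "pigback_format_error")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L)
    pigback_error("PLY header has no format line", "pigback_format_error")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (fmt == "binary_big_endian")
    pigback_error("big-endian PLY is not supported", "pigback_format_error")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    pigback_error(paste0("unsupported PLY format: ", fmt),
                  "pigback_format_error")

  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character(),
                  is_list = logical(), list_count_type = character())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5])
        cur$types <- c(cur$types, tok[4])
        cur$is_list <- c(cur$is_list, TRUE)
        cur$list_count_type <- c(cur$list_count_type, tok[3])
      } else {
        cur$props <- c(cur$props, tok[3])
        cur$types <- c(cur$types, tok[2])
        cur$is_list <- c(cur$is_list, FALSE)
        cur$list_count_type <- c(cur$list_count_type, NA_character_)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (!"vertex" %in% names(elements))
    pigback_error("PLY file has no vertex element", "pigback_format_error")
  vx <- elements[["vertex"]]
  for (p in c("x", "y", "z")) {
    if (!p %in% vx$props)
      pigback_error(paste0("vertex element is missing property '", p, "'"),
                    "pigback_format_error")
  }
  if (any(vx$is_list))
    pigback_error("list properties on the vertex element are not supported",
                  "pigback_format_error")

  if (fmt == "ascii") {
    body <- readLines(con)
    tokens <- scan(text = body, what = character(), quiet = TRUE)
    pos <- 1L
    coords <- NULL
    for (el in elements) {
      if (any(el$is_list) && el$name != "vertex") {
        # variable-length rows: walk token by token
        if (el$name == "vertex") stop("unreachable")
        for (r in seq_len(el$count)) {
          for (pi in seq_along(el$props)) {
            if (el$is_list[pi]) {
              cnt <- as.integer(tokens[pos]); pos <- pos + 1L + cnt
            } else pos <- pos + 1L
          }
        }
        next
      }
      nv <- el$count * length(el$props)
      if (nv == 0L) {
        if (el$name == "vertex") coords <- matrix(numeric(0), ncol = 3L)
        next
      }
      vals <- suppressWarnings(as.numeric(tokens[pos:(pos + nv - 1L)]))
      if (anyNA(vals))
        pigback_error(paste0("non-numeric data in PLY element '", el$name, "'"),
                      "pigback_format_error")
      pos <- pos + nv
      if (el$name == "vertex") {
        m <- matrix(vals, nrow = el$count, ncol = length(el$props),
                    byrow = TRUE)
        coords <- m[, match(c("x", "y", "z"), el$props), drop = FALSE]
      }
    }
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    offset <- 0L
    coords <- NULL
    for (el in elements) {
      if (any(el$is_list))
        pigback_error(
          "list properties in binary PLY are not supported",
          "pigback_format_error")
      sizes <- unname(.ply_sizes[el$types])
      if (anyNA(sizes))
        pigback_error(paste0("unsupported PLY property type in element '",
                             el$name, "'"), "pigback_format_error")
      row_size <- sum(sizes)
      need <- row_size * el$count
      if (offset + need > length(raw))
        pigback_error("binary PLY file truncated", "pigback_format_error")
      if (el$name == "vertex" && el$count > 0L) {
        m <- matrix(NA_real_, nrow = el$count, ncol = 3L)
        starts <- cumsum(c(0L, sizes))
        for (ci in seq_len(3L)) {
          pi <- match(c("x", "y", "z")[ci], el$props)
          s <- sizes[pi]
          sel <- rep(starts[pi] + seq_len(s), times = el$count) +
            rep(seq(0L, by = row_size, length.out = el$count), each = s)
          m[, ci] <- .ply_read_scalar(raw[offset + sel], el$types[pi],
                                      el$count)
        }
        coords <- m
      }
      offset <- offset + need
    }
  }
  if (is.null(coords)) coords <- matrix(numeric(0), ncol = 3L)
  point_cloud(coords)
}

#' Write a point cloud to a PLY file
#'
#' Coordinates are stored as float64 so that `write_ply()` followed by
#' [read_ply()] reproduces them exactly in both dialects.
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"binary"` (little-endian, default) or `"ascii"`.
#' @export
write_ply <- function(cloud, path, format = c("binary", "ascii")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  n <- n_points(cloud)
  fmt_name <- if (format == "ascii") "ascii" else "binary_little_endian"
  header <- c("ply",
              paste("format", fmt_name, "1.0"),
              paste("element vertex", n),
              "property double x", "property double y", "property double z",
              "end_header")
  con <- tryCatch(file(path, "wb"), error = function(e)
    pigback_error(paste0("cannot open '", path, "' for writing"),
                  "pigback_io_error"))
  on.exit(close(con))
  writeLines(header, con)
  if (n > 0L) {
    if (format == "ascii") {
      writeLines(apply(cloud$points, 1L, function(r)
        paste(sprintf("%.17g", r), collapse = " ")), con)
    } else {
      writeBin(as.vector(t(cloud$points)), con, size = 8L, endian = "little")
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# feature tables

FEATURE_COLS <- c("envelope_volume", "envelope_area", "projection_area",
                  "shoulder_width", "belly_width", "hip_width")

#' Construct a back feature record
#'
#' The six back body-size parameters: convex-envelope volume (m^3) and surface
#' area (m^2), planar projection area of the outline (m^2), and the
#' shoulder/belly/hip widths (m).
#'
#' @param envelope_volume,envelope_area,projection_area,shoulder_width,belly_width,hip_width
#'   numeric scalars, all non-negative.
#' @return named numeric vector of class `back_features`.
#' @export
back_features <- function(envelope_volume, envelope_area, projection_area,
                          shoulder_width, belly_width, hip_width) {
  v <- c(envelope_volume = envelope_volume, envelope_area = envelope_area,
         projection_area = projection_area, shoulder_width = shoulder_width,
         belly_width = belly_width, hip_width = hip_width)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all back features must be finite and non-negative")
  structure(v, class = "back_features")
}

#' Read a back-feature table from CSV
#'
#' Expects the header
#' `id,envelope_volume,envelope_area,projection_area,shoulder_width,belly_width,hip_width`
#' with an optional trailing `actual_weight` column (kg). Decimal separator is
#' always the dot, independent of locale.
#'
#' @param path path to a CSV file.
#' @return data frame with one row per record; `actual_weight` is `NA` when
#'   the column is absent.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    pigback_error(paste0("cannot read feature table: ", path),
                  "pigback_io_error")
  df <- read.csv(path, colClasses = "character", check.names = TRUE)
  required <- c("id", FEATURE_COLS)
  missing <- setdiff(required, names(df))
  if (length(missing))
    pigback_error(paste0("feature table is missing required column(s): ",
                         paste(missing, collapse = ", ")),
                  "pigback_schema_error")
  has_w <- "actual_weight" %in% names(df)
  numcols <- c(FEATURE_COLS, if (has_w) "actual_weight")
  for (cl in numcols) {
    vals <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(vals) & !(trimws(df[[cl]]) %in% c("", "NA")))
    if (length(bad))
      pigback_error(sprintf("non-numeric value in column '%s' at row %d",
                            cl, bad[1]), "pigback_parse_error")
    df[[cl]] <- vals
  }
  if (!has_w) df$actual_weight <- rep(NA_real_, nrow(df))
  df[, c("id", FEATURE_COLS, "actual_weight")]
}

#' Write a back-feature table to CSV
#'
#' @param df data frame with columns `id`, the six feature columns and
#'   optionally `actual_weight`.
#' @param path output path.
#' @export
write_feature_table <- function(df, path) {
  required <- c("id", FEATURE_COLS)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "))
  keep <- c("id", FEATURE_COLS,
            if ("actual_weight" %in% names(df) &&
                any(!is.na(df$actual_weight))) "actual_weight")
  write.csv(df[, keep, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# scene ground truth

#' Construct scene ground truth
#'
#' Synthetic stand-in for the scale reading paired with each recorded cloud:
#' the true weight, the body dimensions it was derived from, and per-label
#' point counts.
#'
#' @param true_weight kg, positive.
#' @param body_length,body_width,body_height metres.
#' @param label_counts named integer vector over [POINT_LABELS] subsets.
#' @return an object of class `scene_truth`.
#' @export
scene_truth <- function(true_weight, body_length, body_width, body_height,
                        label_counts) {
  if (!is.finite(true_weight) || true_weight <= 0)
    stop("true_weight must be positive")
  structure(list(true_weight = true_weight, body_length = body_length,
                 body_width = body_width, body_height = body_height,
                 label_counts = label_counts),
            class = "scene_truth")
}

#' Write scene ground truth as a JSON sidecar
#' @param truth a [scene_truth()].
#' @param path output path.
#' @export
write_scene_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scene_truth"))
  jsonlite::write_json(
    list(true_weight = truth$true_weight, body_length = truth$body_length,
         body_width = truth$body_width, body_height = truth$body_height,
         label_counts = as.list(truth$label_counts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene ground-truth JSON sidecar
#' @param path path written by [write_scene_truth()].
#' @return a [scene_truth()].
#' @export
read_scene_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scene_truth(x$true_weight, x$body_length, x$body_width, x$body_height,
              unlist(x$label_counts))
}
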