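#' Read a TRC marker-trajectory file
#'
#' TRC is the tab-separated marker-trajectory dialect used throughout the
#' optical motion-capture ecosystem. Positions are converted to internal
#' meters on read; [write_trc()] writes millimeters (`Units mm`) for
#' interoperability with existing viewers.
#'
#' @param path Path to a `.trc` file.
#' @return A [marker_set()].
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("TRC parse error at line ", length(lines),
                              ": file too short")
  hdr_names <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hdr_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  units <- hdr[["Units"]]
  if (is.null(units)) stop("TRC parse error at line 2: missing Units field")
  n_markers <- as.integer(hdr[["NumMarkers"]])
  n_frames <- as.integer(hdr[["NumFrames"]])
  cols <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  marker_names <- cols[cols != "" & !cols %in% c("Frame#", "Time")]
  if (length(marker_names) != n_markers) {
    stop("TRC parse error at line 4: header declares ", n_markers,
         " markers but ", length(marker_names), " marker columns found")
  }
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_frames) {
    stop("TRC parse error at line 6: expected ", n_frames,
         " data rows, found ", length(body))
  }
  mat <- do.call(rbind, lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\t", fixed = TRUE)[[1]]))
    if (length(v) != 2 + 3 * n_markers || anyNA(v)) {
      stop("TRC parse error at line ", 5 + i, ": expected ",
           2 + 3 * n_markers, " numeric fields")
    }
    v
  }))
  times <- mat[, 2]
  if (any(diff(times) <= 0)) stop("TRC parse error: non-monotonic time")
  scale <- switch(units, mm = 1e-3, m = 1, cm = 1e-2,
                  stop("TRC parse error at line 3: unknown Units '", units, "'"))
  pos <- array(NA_real_, dim = c(nrow(mat), n_markers, 3))
  for (m in seq_len(n_markers)) {
    pos[, m, ] <- mat[, 2 + (m - 1) * 3 + 1:3] * scale
  }
  marker_set(times, pos, marker_names)
}

#' Write a TRC marker-trajectory file
#'
#' @param markers A [marker_set()].
#' @param path Output path.
#' @param data_rate Sampling rate (Hz); inferred from times by default.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, path, data_rate = NULL) {
  nm <- length(markers$marker_names)
  if (nm == 0) stop("cannot write a TRC file with no markers")
  nf <- length(markers$times)
  if (is.null(data_rate)) {
    data_rate <- if (nf > 1) 1 / median(diff(markers$times)) else 60
  }
  l1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  l2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
              collapse = "\t")
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  l3 <- paste(fmt(data_rate), fmt(data_rate), nf, nm, "mm",
              fmt(data_rate), 1, nf, sep = "\t")
  name_cells <- as.vector(rbind(markers$marker_names, "", ""))
  l4 <- paste(c("Frame#", "Time", name_cells[-length(name_cells)]),
              collapse = "\t")
  l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                               rep(seq_len(nm), each = 3))), collapse = "\t")
  pos_mm <- markers$positions / 1e-3
  rows <- vapply(seq_len(nf), function(i) {
    xyz <- as.vector(t(pos_mm[i, , , drop = TRUE]))
    if (nm == 1) xyz <- pos_mm[i, 1, ]
    paste(c(i, fmt(markers$times[i]), fmt(xyz)), collapse = "\t")
  }, character(1))
  writeLines(c(l1, l2, l3, l4, l5, rows), path)
  invisible(path)
}

#' Read an OpenSim-style motion / storage (MOT, STO) file
#'
#' The header is a set of free `key=value` lines terminated by `endheader`;
#' rotational columns are converted to radians internally when
#' `inDegrees=yes`. Columns whose names match `degree_pattern` are treated as
#' rotational.
#'
#' @param path Path to a `.mot`/`.sto` file.
#' @param degree_pattern Regular expression selecting rotational columns; the
#'   default treats all non-`time`, non-translation (`_tx/_ty/_tz`) columns
#'   as rotational.
#' @return A tibble (first column `time`), with attribute `in_degrees`
#'   recording the on-disk convention.
#' @export
read_motion <- function(path, degree_pattern = NULL) {
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0) stop("MOT parse error: missing endheader sentinel")
  end <- end[1]
  hdr <- lines[seq_len(end - 1)]
  get_field <- function(key) {
    m <- grep(paste0("^\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(m) == 0) return(NA_character_)
    trimws(sub(".*=", "", m[1]))
  }
  in_degrees <- identical(tolower(get_field("inDegrees")), "yes")
  n_rows <- suppressWarnings(as.integer(get_field("nRows")))
  n_cols <- suppressWarnings(as.integer(get_field("nColumns")))
  cols <- strsplit(lines[end + 1], "\t", fixed = TRUE)[[1]]
  cols <- cols[nzchar(cols)]
  if (cols[1] != "time") stop("MOT parse error at line ", end + 1,
                              ": first column must be 'time'")
  if (!is.na(n_cols) && n_cols != length(cols)) {
    stop("MOT parse error: nColumns=", n_cols, " but ",
         length(cols), " columns found")
  }
  body <- lines[-(1:(end + 1))]
  body <- body[nzchar(trimws(body))]
  if (!is.na(n_rows) && length(body) != n_rows) {
    stop("MOT parse error: expected ", n_rows, " rows, found ", length(body))
  }
  mat <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  colnames(mat) <- cols
  df <- tibble::as_tibble(as.data.frame(mat))
  if (in_degrees) {
    rot <- if (is.null(degree_pattern)) {
      setdiff(cols[-1], grep("_t[xyz]$", cols, value = TRUE))
    } else grep(degree_pattern, cols[-1], value = TRUE)
    for (cc in rot) df[[cc]] <- df[[cc]] * pi / 180
  }
  attr(df, "in_degrees") <- in_degrees
  df
}

#' Write a motion / storage file
#'
#' @param df Data frame whose first column is `time`.
#' @param path Output path.
#' @param in_degrees Write rotational columns in degrees (`inDegrees=yes`),
#'   the ecosystem convention.
#' @param degree_pattern As in [read_motion()].
#' @return `path`, invisibly.
#' @export
write_motion <- function(df, path, in_degrees = TRUE, degree_pattern = NULL) {
  df <- as.data.frame(df)
  if (ncol(df) < 2) stop("cannot write a motion file with no data columns")
  if (names(df)[1] != "time") {
    tix <- match("time", names(df))
    if (is.na(tix)) stop("motion table must contain a 'time' column")
    df <- df[, c(tix, setdiff(seq_along(df), tix))]  # time column always first
  }
  out <- df
  if (in_degrees) {
    rot <- if (is.null(degree_pattern)) {
      setdiff(names(df)[-1], grep("_t[xyz]$", names(df), value = TRUE))
    } else grep(degree_pattern, names(df)[-1], value = TRUE)
    for (cc in rot) out[[cc]] <- out[[cc]] * 180 / pi
  }
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  hdr <- c(basename(path),
           "version=1",
           paste0("nRows=", nrow(out)),
           paste0("nColumns=", ncol(out)),
           paste0("inDegrees=", if (in_degrees) "yes" else "no"),
           "endheader",
           paste(names(out), collapse = "\t"))
  rows <- apply(out, 1, function(r) paste(fmt(r), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a per-camera 2D keypoint CSV
#'
#' One CSV per camera with columns `frame`, `time`, then `x`/`y`/`confidence`
#' triplets per keypoint, named `<keypoint>_x`, `<keypoint>_y`,
#' `<keypoint>_c`. Keypoint names are validated against the 20-name canon and
#' reordered canonically; confidences outside \[0, 1\] are clamped with a
#' warning.
#'
#' @param path CSV path.
#' @param camera_id Camera identifier (default: file stem).
#' @return A [keypoint_series_2d()].
#' @export
read_keypoints <- function(path, camera_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(camera_id)) camera_id <- sub("\\.[^.]*$", "", basename(path))
  if (!all(c("frame", "time") %in% names(df))) {
    stop("keypoint CSV must have 'frame' and 'time' columns")
  }
  if (any(df$frame < 0)) stop("negative frame index in keypoint file")
  kp_cols <- setdiff(names(df), c("frame", "time"))
  kp_names <- unique(sub("_(x|y|c)$", "", kp_cols))
  unknown <- setdiff(kp_names, keypoint_canon())
  if (length(unknown)) stop("unknown keypoint name(s): ",
                            paste(unknown, collapse = ", "))
  if (!setequal(kp_names, keypoint_canon())) {
    stop("keypoint CSV must contain all 20 canonical keypoints; missing: ",
         paste(setdiff(keypoint_canon(), kp_names), collapse = ", "))
  }
  nf <- nrow(df)
  pos <- array(NA_real_, dim = c(nf, 20, 2))
  conf <- matrix(NA_real_, nf, 20)
  for (k in seq_along(keypoint_canon())) {
    nm <- keypoint_canon()[k]
    pos[, k, 1] <- df[[paste0(nm, "_x")]]
    pos[, k, 2] <- df[[paste0(nm, "_y")]]
    conf[, k] <- df[[paste0(nm, "_c")]]
  }
  keypoint_series_2d(camera_id, df$time, pos, conf, keypoint_canon())
}

#' Write a per-camera 2D keypoint CSV
#'
#' @param series A [keypoint_series_2d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(series, path) {
  nf <- length(series$times)
  df <- data.frame(frame = seq_len(nf) - 1L, time = series$times)
  for (k in seq_along(series$keypoint_names)) {
    nm <- series$keypoint_names[k]
    df[[paste0(nm, "_x")]] <- series$positions[, k, 1]
    df[[paste0(nm, "_y")]] <- series$positions[, k, 2]
    df[[paste0(nm, "_c")]] <- series$confidence[, k]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write camera parameters as JSON
#'
#' JSON schema: `intrinsics {fx, fy, cx, cy, distortion:[k1,k2,p1,p2,k3],
#' image_size:[w,h]}` and `extrinsics {rotation_vector:[3], translation:[3]}`
#' (meters, world-to-camera).
#'
#' @param path JSON path.
#' @return A `camera` object (see [camera()]).
#' @export
read_camera_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera(
    intrinsics = camera_intrinsics(
      fx = j$intrinsics$fx, fy = j$intrinsics$fy,
      cx = j$intrinsics$cx, cy = j$intrinsics$cy,
      distortion = as.numeric(j$intrinsics$distortion),
      image_size = as.numeric(j$intrinsics$image_size)),
    extrinsics = camera_extrinsics(
      rotation_vector = as.numeric(j$extrinsics$rotation_vector),
      translation = as.numeric(j$extrinsics$translation))
  )
}

#' @rdname read_camera_json
#' @param cam A `camera` object.
#' @export
write_camera_json <- function(cam, path) {
  j <- list(
    intrinsics = list(fx = cam$intrinsics$fx, fy = cam$intrinsics$fy,
                      cx = cam$intrinsics$cx, cy = cam$intrinsics$cy,
                      distortion = cam$intrinsics$distortion,
                      image_size = cam$intrinsics$image_size),
    extrinsics = list(rotation_vector = cam$extrinsics$rotation_vector,
                      translation = cam$extrinsics$translation)
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundle describing one recorded trial
#'
#' @param subject_id Subject identifier.
#' @param height Subject height (m), > 0.
#' @param mass Subject mass (kg), > 0.
#' @param task_label One of `walk`, `squat`, `sit_to_stand`, `drop_jump`,
#'   `other`.
#' @param keypoint_files Named character vector of per-camera keypoint CSVs.
#' @param camera_files Named character vector of camera JSONs.
#' @param sampling_rate Acquisition rate (Hz), > 0.
#' @return A `trial_bundle` object; all referenced files are checked to exist
#'   and parse at construction.
#' @export
trial_bundle <- function(subject_id, height, mass, task_label,
                         keypoint_files, camera_files, sampling_rate = 60) {
  stopifnot(height > 0, mass > 0, sampling_rate > 0)
  task_label <- match.arg(task_label,
                          c("walk", "squat", "sit_to_stand", "drop_jump", "other"))
  missing <- c(keypoint_files, camera_files)
  missing <- missing[!file.exists(missing)]
  if (length(missing)) stop("referenced file(s) not found: ",
                            paste(missing, collapse = ", "))
  series <- lapply(keypoint_files, read_keypoints)
  cams <- lapply(camera_files, read_camera_json)
  structure(list(subject_id = subject_id, height = height, mass = mass,
                 task_label = task_label, keypoints = series, cameras = cams,
                 sampling_rate = sampling_rate),
            class = "trial_bundle")
}
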