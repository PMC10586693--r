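#' Pipeline data containers
#'
#' Lightweight S3 containers with matrix payloads. Positions are stored as
#' `frames x keypoints/markers x 3` arrays (meters) or `frames x keypoints x 2`
#' arrays (pixels); all time bases are uniform and in seconds. Internal units
#' are SI (meters, radians) everywhere past the file readers.
#'
#' @name containers
NULL

#' Construct a 2D keypoint series
#'
#' @param camera_id Camera identifier.
#' @param times Strictly increasing, uniform time stamps (s).
#' @param positions `frames x 20 x 2` array of pixel coordinates.
#' @param confidence `frames x 20` matrix in \[0, 1\].
#' @param keypoint_names Keypoint names; must be a permutation of
#'   [keypoint_canon()]. Data are reordered to canonical order.
#' @return A `keypoint_series_2d` object.
#' @export
keypoint_series_2d <- function(camera_id, times, positions, confidence,
                               keypoint_names = keypoint_canon()) {
  times <- as.numeric(times)
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3] == 2L)
  if (!setequal(keypoint_names, keypoint_canon()) ||
      length(keypoint_names) != 20L) {
    bad <- setdiff(keypoint_names, keypoint_canon())
    stop("keypoint names must match the 20-name canon; unknown: ",
         paste(bad, collapse = ", "))
  }
  ord <- match(keypoint_canon(), keypoint_names)
  positions <- positions[, ord, , drop = FALSE]
  confidence <- as.matrix(confidence)[, ord, drop = FALSE]
  check_uniform_times(times)
  if (any(confidence < 0 | confidence > 1)) {
    warning("confidence values outside [0, 1] were clamped")
    confidence[] <- pmin(pmax(confidence, 0), 1)
  }
  dimnames(positions) <- list(NULL, keypoint_canon(), c("x", "y"))
  colnames(confidence) <- keypoint_canon()
  structure(list(camera_id = camera_id,
                 frame_rate = 1 / median(diff(times)),
                 times = times, positions = positions,
                 confidence = confidence,
                 keypoint_names = keypoint_canon()),
            class = "keypoint_series_2d")
}

check_uniform_times <- function(times) {
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (diff(range(dt)) > 1e-9) stop("times must be uniform to within 1e-9 s")
  }
  invisible(times)
}

#' Construct a 3D keypoint series
#'
#' @param times Time stamps (s).
#' @param positions `frames x 20 x 3` array (m).
#' @param validity Logical `frames x 20` matrix; invalid entries carry `NA`
#'   positions.
#' @param keypoint_names Canonical keypoint names.
#' @return A `keypoint_series_3d` object.
#' @export
keypoint_series_3d <- function(times, positions, validity = NULL,
                               keypoint_names = keypoint_canon()) {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3] == 3L)
  check_uniform_times(times)
  if (is.null(validity)) {
    validity <- !apply(is.na(positions) | is.infinite(positions), c(1, 2), any)
  }
  validity <- matrix(as.logical(validity), nrow = dim(positions)[1])
  # invalid entries carry no position
  mask <- array(rep(!validity, 3), dim = dim(positions))
  positions[mask] <- NA_real_
  if (any(!is.finite(positions[!mask]))) stop("valid positions must be finite")
  dimnames(positions) <- list(NULL, keypoint_names, c("x", "y", "z"))
  structure(list(times = as.numeric(times), positions = positions,
                 validity = validity, keypoint_names = keypoint_names),
            class = "keypoint_series_3d")
}

#' Construct a marker trajectory set
#'
#' @param times Time stamps (s).
#' @param positions `frames x n_markers x 3` array (m).
#' @param marker_names Unique marker names.
#' @return A `marker_set` object.
#' @export
marker_set <- function(times, positions, marker_names) {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3] == 3L,
            dim(positions)[2] == length(marker_names))
  if (anyDuplicated(marker_names)) stop("marker names must be unique")
  check_uniform_times(times)
  dimnames(positions) <- list(NULL, marker_names, c("x", "y", "z"))
  structure(list(times = as.numeric(times), positions = positions,
                 marker_names = marker_names),
            class = "marker_set")
}

#' Construct a generalized-coordinate trajectory
#'
#' Holds q(t) for an articulated model (radians for rotational coordinates,
#' meters for translational ones), optionally with derivatives.
#'
#' @param times Time stamps (s).
#' @param q `frames x n_coordinates` matrix with column names.
#' @param qd,qdd Optional derivative matrices of the same shape.
#' @return A `coordinate_trajectory` object.
#' @export
coordinate_trajectory <- function(times, q, qd = NULL, qdd = NULL) {
  q <- as.matrix(q)
  check_uniform_times(times)
  stopifnot(nrow(q) == length(times), !is.null(colnames(q)))
  structure(list(times = as.numeric(times), q = q, qd = qd, qdd = qdd),
            class = "coordinate_trajectory")
}

#' @export
print.keypoint_series_2d <- function(x, ...) {
  cat("<keypoint_series_2d> camera", x$camera_id, "-",
      length(x$times), "frames @", round(x$frame_rate, 3), "Hz\n")
  invisible(x)
}

#' @export
print.keypoint_series_3d <- function(x, ...) {
  cat("<keypoint_series_3d>", length(x$times), "frames,",
      round(100 * mean(x$validity), 1), "% valid\n")
  invisible(x)
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set>", length(x$marker_names), "markers,",
      length(x$times), "frames\n")
  invisible(x)
}

#' @export
print.coordinate_trajectory <- function(x, ...) {
  cat("<coordinate_trajectory>", ncol(x$q), "coordinates,",
      length(x$times), "frames\n")
  invisible(x)
}

#' Tidy a coordinate trajectory into a long tibble
#'
#' @param x A `coordinate_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `coordinate`, `value` (and
#'   `velocity`/`acceleration` when present).
#' @export
tidy.coordinate_trajectory <- function(x, ...) {
  out <- tibble::tibble(
    time = rep(x$times, times = ncol(x$q)),
    coordinate = rep(colnames(x$q), each = nrow(x$q)),
    value = as.vector(x$q)
  )
  if (!is.null(x$qd)) out$velocity <- as.vector(x$qd)
  if (!is.null(x$qdd)) out$acceleration <- as.vector(x$qdd)
  out
}

#' Tidy a marker set into a long tibble
#' @param x A `marker_set`.
#' @param ... Unused.
#' @export
tidy.marker_set <- function(x, ...) {
  nm <- length(x$marker_names)
  nf <- length(x$times)
  tibble::tibble(
    time = rep(x$times, times = nm),
    marker = rep(x$marker_names, each = nf),
    x = as.vector(x$positions[, , 1]),
    y = as.vector(x$positions[, , 2]),
    z = as.vector(x$positions[, , 3])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coordinate trajectory
#'
#' @param object A `coordinate_trajectory`.
#' @param ... Unused.
#' @return A ggplot object, one facet per coordinate.
#' @export
autoplot.coordinate_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~coordinate, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "coordinate (rad | m)")
}

#' @importFrom rlang .data
NULL
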