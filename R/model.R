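#' Articulated skeletal model
#'
#' A model is a tree of rigid segments rooted at the pelvis. Each segment
#' attaches to its parent through a joint defined by a fixed location in the
#' parent frame and an ordered sequence of single-axis degrees of freedom
#' (rotations about, or translations along, fixed local axes), each actuated
#' by exactly one named generalized coordinate. Segments carry mass, a
#' diagonal body-frame inertia, a center of mass, and local marker / keypoint
#' attachments. Optional muscle paths (via-point polylines), ideal torque
#' motors, and foot-ground contact spheres make the model dynamics-capable.
#'
#' @param segments List of segment definitions (see [load_model()] for the
#'   YAML schema).
#' @param muscles,torque_motors,contact_spheres Optional actuator / contact
#'   definitions.
#' @param gravity Gravity vector (m/s^2), default `c(0, -9.81, 0)` (y-up).
#' @param name Model name.
#' @return A validated `skeletal_model` object.
#' @export
skeletal_model <- function(segments, muscles = list(), torque_motors = list(),
                           contact_spheres = list(),
                           gravity = c(0, -GRAVITY, 0), name = "model") {
  seg_names <- vapply(segments, `[[`, character(1), "name")
  if (anyDuplicated(seg_names)) stop("duplicate segment names")
  parents <- vapply(segments, `[[`, character(1), "parent")
  roots <- seg_names[parents == "ground"]
  if (length(roots) != 1) stop("model must have exactly one root segment")
  bad <- setdiff(parents, c("ground", seg_names))
  if (length(bad)) stop("orphan segment parent(s): ", paste(bad, collapse = ", "))
  # topological order + cycle detection
  order <- character(0)
  remaining <- seg_names
  placed <- "ground"
  while (length(remaining)) {
    nxt <- remaining[parents[match(remaining, seg_names)] %in% placed]
    if (!length(nxt)) stop("cyclic parent graph involving: ",
                           paste(remaining, collapse = ", "))
    order <- c(order, nxt)
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  segments <- segments[match(order, seg_names)]
  # coordinate table
  coords <- list()
  for (s in segments) {
    for (d in s$joint$dofs) {
      coords[[length(coords) + 1]] <- tibble::tibble(
        name = d$coordinate, type = d$type, segment = s$name,
        lower = d$bounds[1], upper = d$bounds[2])
    }
  }
  coords <- if (length(coords)) dplyr::bind_rows(coords) else
    tibble::tibble(name = character(), type = character(),
                   segment = character(), lower = numeric(), upper = numeric())
  if (anyDuplicated(coords$name)) stop("duplicate coordinate names")
  mk <- unlist(lapply(segments, function(s) names(s$markers)))
  if (anyDuplicated(mk)) stop("duplicate marker names across segments")
  structure(list(name = name, gravity = as.numeric(gravity),
                 segments = segments, coordinates = coords,
                 muscles = muscles, torque_motors = torque_motors,
                 contact_spheres = contact_spheres,
                 n_coordinates = nrow(coords)),
            class = "skeletal_model")
}

#' @export
print.skeletal_model <- function(x, ...) {
  cat("<skeletal_model>", x$name, "-", length(x$segments), "segments,",
      x$n_coordinates, "coordinates,", length(x$muscles), "muscles,",
      length(x$torque_motors), "torque motors,",
      length(x$contact_spheres), "contact spheres\n")
  invisible(x)
}

#' Load a skeletal model from its YAML definition
#'
#' The schema mirrors [skeletal_model()]: top-level keys `name`, `gravity`,
#' `segments`, and optional `muscles`, `torque_motors`, `contact_spheres`.
#' Each segment: `name`, `parent`, `mass`, `com`, `inertia`, `joint:
#' {location_in_parent, location_in_child, dofs: [{coordinate, type, axis,
#' bounds}]}`, `markers: {name: [x,y,z]}`, `keypoints: {...}`, optional
#' `scale_pair: [markerA, markerB]`.
#'
#' @param path YAML file path.
#' @return A `skeletal_model`.
#' @export
load_model <- function(path) {
  y <- yaml::read_yaml(path)
  model_from_list(y)
}

model_from_list <- function(y) {
  segs <- lapply(y$segments, function(s) {
    s$com <- as.numeric(s$com %||% c(0, 0, 0))
    s$inertia <- as.numeric(s$inertia %||% c(1e-3, 1e-3, 1e-3))
    s$joint$location_in_parent <-
      as.numeric(s$joint$location_in_parent %||% c(0, 0, 0))
    s$joint$location_in_child <-
      as.numeric(s$joint$location_in_child %||% c(0, 0, 0))
    s$joint$dofs <- lapply(s$joint$dofs %||% list(), function(d) {
      d$axis <- as.numeric(d$axis)
      d$bounds <- as.numeric(d$bounds %||% c(-Inf, Inf))
      d
    })
    s$markers <- lapply(s$markers %||% list(), as.numeric)
    s$keypoints <- lapply(s$keypoints %||% list(), as.numeric)
    s
  })
  mus <- lapply(y$muscles %||% list(), function(m) {
    m$path <- lapply(m$path, function(p) {
      p$location <- as.numeric(p$location); p
    })
    m
  })
  cs <- lapply(y$contact_spheres %||% list(), function(s) {
    s$location <- as.numeric(s$location); s
  })
  skeletal_model(segs, muscles = mus,
                 torque_motors = y$torque_motors %||% list(),
                 contact_spheres = cs,
                 gravity = as.numeric(y$gravity %||% c(0, -GRAVITY, 0)),
                 name = y$name %||% "model")
}

#' Serialize a skeletal model to YAML
#' @param model A `skeletal_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  y <- list(name = model$name, gravity = model$gravity,
            segments = model$segments, muscles = model$muscles,
            torque_motors = model$torque_motors,
            contact_spheres = model$contact_spheres)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale a model to a subject's anthropometry
#'
#' Per-segment uniform scale factors are the ratios of measured to default
#' inter-marker distances (for the segment's declared `scale_pair`),
#' time-averaged over a neutral standing trial. Segments without a pair
#' inherit their parent's factor (the root defaults to 1). Segment masses are
#' scaled to the subject's total mass preserving the default mass fractions;
#' attachments, joint locations, muscle path points, and contact spheres
#' scale with their segments; inertias scale with mass times factor squared.
#'
#' @param model A `skeletal_model`.
#' @param neutral_markers [marker_set()] of a neutral standing trial
#'   (>= 0.5 s recommended).
#' @param height Subject height (m); stored on the result.
#' @param mass Subject mass (kg).
#' @return List with `model` (scaled) and `scale_factors` (named vector).
#' @export
scale_model <- function(model, neutral_markers, height, mass) {
  seg_names <- vapply(model$segments, `[[`, character(1), "name")
  # default (model-frame) marker positions at the default pose
  q0 <- stats::setNames(rep(0, model$n_coordinates), model$coordinates$name)
  def <- forward_kinematics(model, q0)
  meas <- neutral_markers$positions
  factors <- stats::setNames(rep(NA_real_, length(seg_names)), seg_names)
  missing_marks <- character(0)
  for (i in seq_along(model$segments)) {
    s <- model$segments[[i]]
    pair <- s$scale_pair
    if (is.null(pair)) next
    if (!all(pair %in% neutral_markers$marker_names)) {
      missing_marks <- c(missing_marks, setdiff(pair, neutral_markers$marker_names))
      next
    }
    if (!all(pair %in% rownames(def$markers))) next
    d_def <- sqrt(sum((def$markers[pair[1], ] - def$markers[pair[2], ])^2))
    i1 <- match(pair[1], neutral_markers$marker_names)
    i2 <- match(pair[2], neutral_markers$marker_names)
    d_meas <- mean(sqrt(rowSums((meas[, i1, , drop = TRUE] -
                                   meas[, i2, , drop = TRUE])^2)))
    factors[i] <- d_meas / d_def
  }
  if (length(missing_marks)) {
    stop("missing required scaling markers: ",
         paste(unique(missing_marks), collapse = ", "))
  }
  # inherit from parent where undefined
  for (i in seq_along(model$segments)) {
    if (is.na(factors[i])) {
      par <- model$segments[[i]]$parent
      factors[i] <- if (par == "ground") 1 else factors[par]
      if (is.na(factors[i])) factors[i] <- 1
    }
  }
  default_masses <- vapply(model$segments, `[[`, numeric(1), "mass")
  new_masses <- default_masses / sum(default_masses) * mass
  scaled_segments <- lapply(seq_along(model$segments), function(i) {
    s <- model$segments[[i]]
    f <- factors[s$name]
    fp <- if (s$parent == "ground") 1 else factors[s$parent]
    s$joint$location_in_parent <- s$joint$location_in_parent * fp
    s$joint$location_in_child <- s$joint$location_in_child * f
    s$com <- s$com * f
    s$inertia <- s$inertia * (new_masses[i] / s$mass) * f^2
    s$mass <- new_masses[i]
    s$markers <- lapply(s$markers, function(p) p * f)
    s$keypoints <- lapply(s$keypoints, function(p) p * f)
    s
  })
  mus <- lapply(model$muscles, function(m) {
    m$path <- lapply(m$path, function(p) {
      p$location <- p$location * factors[p$segment]
      p
    })
    # optimal fiber / slack lengths scale with the average of the segments
    # the path spans
    fbar <- mean(factors[vapply(m$path, `[[`, character(1), "segment")])
    m$l_opt <- m$l_opt * fbar
    m$l_slack <- m$l_slack * fbar
    m
  })
  cs <- lapply(model$contact_spheres, function(s) {
    s$location <- s$location * factors[s$segment]
    s
  })
  scaled <- skeletal_model(scaled_segments, muscles = mus,
                           torque_motors = model$torque_motors,
                           contact_spheres = cs, gravity = model$gravity,
                           name = paste0(model$name, "_scaled"))
  scaled$subject <- list(height = height, mass = mass)
  list(model = scaled, scale_factors = factors)
}
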