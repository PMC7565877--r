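# Channel pathway exploration: iteratively place path points at maximal
# clearance from surrounding atoms, then profile the minimal radius along
# the resulting axis per trajectory frame.

#' Pathway exploration specification
#'
#' @param start_point 3-vector (Angstrom), at or outside the channel mouth;
#'   must have positive clearance.
#' @param target_point 3-vector (Angstrom), the buried terminus the path is
#'   anchored to (e.g. the centroid of the i+1 or i+2 register selection).
#' @param step_length step between consecutive path points (Angstrom).
#' @param search_radius radius of the orthogonal disc used for per-point
#'   refinement; must be >= `step_length`.
#' @param max_points hard cap on the number of path points.
#' @return a `PathwaySpec`.
#' @export
pathway_spec <- function(start_point, target_point, step_length = 1,
                         search_radius = NULL, max_points = 500L) {
  if (is.null(search_radius)) search_radius <- 2 * step_length
  stopifnot(length(start_point) == 3L, length(target_point) == 3L,
            step_length > 0, search_radius >= step_length, max_points >= 2L)
  structure(list(start_point = as.numeric(start_point),
                 target_point = as.numeric(target_point),
                 step_length = step_length,
                 search_radius = search_radius,
                 max_points = as.integer(max_points)),
            class = "PathwaySpec")
}

#' Signed clearance of a point from a structure
#'
#' The scalar the pathway algorithm maximizes: the minimum over atoms of the
#' Euclidean distance from the point to the atom center minus the atom's van
#' der Waals radius. Negative iff the point lies inside some atom's sphere;
#' the sign is retained so transient clashes in MD frames are diagnosable.
#'
#' @param point 3-vector (Angstrom).
#' @param structure a `MolecularStructure`, or a list with elements `xyz`
#'   (n x 3 matrix) and `radii` (length-n numeric).
#' @return signed clearance in Angstrom.
#' @export
clearance <- function(point, structure) {
  g <- as_geometry(structure)
  clearance_point(point, g$xyz, g$radii)
}

as_geometry <- function(structure) {
  if (inherits(structure, "MolecularStructure")) {
    list(xyz = coords(structure), radii = structure$vdw_radius)
  } else if (is.list(structure) && !is.null(structure$xyz)) {
    list(xyz = as.matrix(structure$xyz), radii = as.numeric(structure$radii))
  } else stop("structure must be a MolecularStructure or list(xyz, radii)")
}

clearance_point <- function(p, xyz, radii) {
  min(sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 +
             (xyz[, 3] - p[3])^2) - radii)
}

# Clearance of many probe points at once (m x 3), chunked to bound memory.
clearance_points <- function(pts, xyz, radii, chunk = 512L) {
  m <- nrow(pts)
  out <- numeric(m)
  for (i0 in seq(1L, m, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, m)
    block <- pts[i0:i1, , drop = FALSE]
    # (b x n) squared distance via outer sums
    d2 <- outer(rowSums(block^2), rowSums(xyz^2), "+") -
      2 * tcrossprod(block, xyz)
    d2[d2 < 0] <- 0
    out[i0:i1] <- apply(sweep(sqrt(d2), 2L, radii, "-"), 1L, min)
  }
  out
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length direction")
  v / n
}

# Orthonormal frame (u, v) completing unit vector w.
orthonormal_frame <- function(w) {
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(pracma_cross(w, a))
  v <- pracma_cross(w, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Quasi-uniform directions on the forward hemisphere around unit vector w.
# Deterministic: a Fibonacci spiral, with an azimuthal offset derived
# arithmetically from the seed (the global RNG is never touched).
hemisphere_directions <- function(w, n = 64L, seed = 0L) {
  frame <- orthonormal_frame(w)
  i <- seq_len(n)
  z <- (i - 0.5) / n
  golden <- pi * (3 - sqrt(5))
  rot <- 2 * pi * ((as.numeric(seed) * 0.6180339887498949) %% 1)
  phi <- golden * i + rot
  r <- sqrt(pmax(0, 1 - z^2))
  t(vapply(seq_len(n), function(k)
    r[k] * cos(phi[k]) * frame$u + r[k] * sin(phi[k]) * frame$v + z[k] * w,
    numeric(3)))
}

# Coordinate descent within the disc {center + a*u + b*v : a^2+b^2 <= radius^2},
# maximizing clearance subject to `feasible(point)`.
refine_in_disc <- function(center, u, v, radius, xyz, radii,
                           feasible = NULL, tol = 0.01) {
  best <- center
  best_cl <- clearance_point(center, xyz, radii)
  offset <- c(0, 0)
  h <- radius / 2
  while (h > tol) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (d in list(c(h, 0), c(-h, 0), c(0, h), c(0, -h))) {
        cand_off <- offset + d
        if (sum(cand_off^2) > radius^2) next
        p <- center + cand_off[1] * u + cand_off[2] * v
        if (!is.null(feasible) && !feasible(p)) next
        cl <- clearance_point(p, xyz, radii)
        if (cl > best_cl + 1e-12) {
          best_cl <- cl; best <- p; offset <- cand_off; improved <- TRUE
        }
      }
    }
    h <- h / 2
  }
  list(point = best, clearance = best_cl)
}

#' Trace a channel pathway by iterative clearance maximization
#'
#' From the current point, candidate next points are sampled at
#' `step_length` on the forward hemisphere (toward the target); the
#' candidate maximizing clearance, subject to net progress toward the
#' target, is locally refined within the orthogonal disc and becomes the
#' next path point. Terminates with success when within `step_length` of
#' the target; returns a flagged partial axis when blocked (no candidate
#' with positive clearance and progress) or when `max_points` is hit.
#' Deterministic for fixed structure, spec and seed.
#'
#' @param structure a `MolecularStructure` (the channel walls).
#' @param spec a [pathway_spec()].
#' @param seed integer controlling the azimuthal offset of the candidate
#'   spiral; the global RNG is not used.
#' @param n_directions candidate directions per step.
#' @return a `PathwayAxis`: list with `points` (m x 3), `clearance`,
#'   `arclength_from_end`, `status` ("reached", "blocked" or "max_points"),
#'   `n_atoms`, `spec`, `seed`.
#' @export
find_path <- function(structure, spec, seed = 0L, n_directions = 64L) {
  stopifnot(inherits(spec, "PathwaySpec"))
  g <- as_geometry(structure)
  xyz <- g$xyz; radii <- g$radii
  step <- spec$step_length
  target <- spec$target_point
  cur <- spec$start_point
  cl0 <- clearance_point(cur, xyz, radii)
  if (cl0 <= 0)
    stop("start point is buried (clearance ", signif(cl0, 3), " <= 0)")
  pts <- list(cur)
  cls <- cl0
  status <- "max_points"
  min_progress <- 0.25 * step
  # refinement stays within a disc small enough to keep consecutive spacing
  # inside [0.5, 1.5] * step_length
  rho <- min(spec$search_radius, 1.1 * step)
  while (length(pts) < spec$max_points) {
    dist_t <- sqrt(sum((cur - target)^2))
    if (dist_t <= step) { status <- "reached"; break }
    w <- unitize(target - cur)
    dirs <- hemisphere_directions(w, n_directions, seed)
    cand <- sweep(dirs * step, 2L, cur, "+")
    cl <- clearance_points(cand, xyz, radii)
    prog <- dist_t - sqrt((cand[, 1] - target[1])^2 +
                            (cand[, 2] - target[2])^2 +
                            (cand[, 3] - target[3])^2)
    ok <- cl > 0 & prog >= min_progress
    if (!any(ok)) { status <- "blocked"; break }
    # max clearance; ties -> greatest progress, then lowest index
    pick <- which(ok)[order(-cl[ok], -prog[ok], which(ok))][1]
    next_pt <- cand[pick, ]
    stepdir <- unitize(next_pt - cur)
    fr <- orthonormal_frame(stepdir)
    cur_fixed <- cur
    feas <- function(p) {
      sqrt(sum((p - target)^2)) <= dist_t - min_progress
    }
    ref <- refine_in_disc(next_pt, fr$u, fr$v, rho, xyz, radii,
                          feasible = feas)
    cur <- ref$point
    pts[[length(pts) + 1L]] <- cur
    cls <- c(cls, ref$clearance)
  }
  if (status == "reached" && length(pts) == 1L) {
    pts[[2L]] <- target
    cls <- c(cls, clearance_point(target, xyz, radii))
  }
  points <- do.call(rbind, pts)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  arc_from_start <- c(0, cumsum(seg))
  total <- arc_from_start[length(arc_from_start)]
  structure(list(points = points, clearance = cls,
                 arclength_from_end = total - arc_from_start,
                 total_length = total,
                 status = status, n_atoms = nrow(xyz),
                 spec = spec, seed = seed),
            class = "PathwayAxis")
}

#' @export
print.PathwayAxis <- function(x, ...) {
  cat(sprintf("PathwayAxis: %d points, length %.1f A, status %s\n",
              nrow(x$points), x$total_length, x$status))
  invisible(x)
}

# Local axis direction at each path point (central differences).
axis_tangents <- function(points) {
  m <- nrow(points)
  t(vapply(seq_len(m), function(i) {
    a <- max(1L, i - 1L); b <- min(m, i + 1L)
    unitize(points[b, ] - points[a, ])
  }, numeric(3)))
}

#' Minimal-radius profile of a pathway over a trajectory
#'
#' For each frame, each path point is re-optimized within a disc (radius
#' `search_radius`) orthogonal to the local axis direction, and its
#' clearance recorded as the frame's minimal radius at that arclength.
#' Values are binned (1 Angstrom bins) by arclength from the pathway end
#' (the buried terminus); the first `trim_start` Angstrom from the entry
#' side are omitted, discounting the initial convergence of the exploration
#' toward the channel center.
#'
#' @param axis a `PathwayAxis` computed on a frame congruent with `traj`.
#' @param traj a `TrajectoryWindow` (or a single `MolecularStructure`,
#'   treated as a one-frame trajectory).
#' @param trim_start Angstrom trimmed from the entry side (default 6).
#' @param search_radius disc radius for per-frame re-optimization; default
#'   taken from the axis spec.
#' @param bin_width profile bin width in Angstrom.
#' @return a `RadiusProfile`: list with `bin_centers` (distance from the
#'   pathway end, ascending), `values` (bins x frames matrix),
#'   `trim_start`, `total_length`, `frame_times`.
#' @export
min_radius_profile <- function(axis, traj, trim_start = 6,
                               search_radius = NULL, bin_width = 1) {
  stopifnot(inherits(axis, "PathwayAxis"))
  if (inherits(traj, "MolecularStructure"))
    traj <- trajectory_window(list(coords(traj)), traj, frame_times = 0)
  if (nrow(traj$frames[[1]]) != axis$n_atoms)
    stop("axis/trajectory topology mismatch: ", axis$n_atoms, " vs ",
         nrow(traj$frames[[1]]), " atoms")
  if (is.null(search_radius)) search_radius <- axis$spec$search_radius
  radii <- traj$topology$vdw_radius
  tang <- axis_tangents(axis$points)
  m <- nrow(axis$points)
  nf <- n_frames(traj)
  point_cl <- matrix(NA_real_, m, nf)
  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]
    for (i in seq_len(m)) {
      fr <- orthonormal_frame(tang[i, ])
      ref <- refine_in_disc(axis$points[i, ], fr$u, fr$v, search_radius,
                            xyz, radii)
      point_cl[i, f] <- ref$clearance
    }
  }
  arc_end <- axis$arclength_from_end
  total <- axis$total_length
  centers <- seq(bin_width / 2, max(arc_end), by = bin_width)
  keep <- centers <= total - trim_start
  centers <- centers[keep]
  if (length(centers) == 0L)
    stop("trim_start leaves no profile bins (pathway too short)")
  ord <- order(arc_end)
  values <- vapply(seq_len(nf), function(f)
    stats::approx(arc_end[ord], point_cl[ord, f], xout = centers,
                  rule = 2)$y,
    numeric(length(centers)))
  values <- matrix(values, nrow = length(centers))
  structure(list(bin_centers = centers, values = values,
                 trim_start = trim_start, total_length = total,
                 frame_times = traj$frame_times),
            class = "RadiusProfile")
}

#' Constriction report for a radius profile
#'
#' Per frame, the global minimum of the profile and its arclength (from
#' both the pathway end and the entry side), plus per-bin temporal variance
#' to flag "circumstantial" segments whose width changes over the window.
#'
#' @param profile a `RadiusProfile`.
#' @return list with `per_frame` (data frame: frame, frame_time,
#'   arclength_from_end, arclength_from_start, min_radius) and
#'   `bin_variance` (data frame: bin_center, variance).
#' @export
constriction_report <- function(profile) {
  stopifnot(inherits(profile, "RadiusProfile"),
            length(profile$bin_centers) > 0L)
  v <- profile$values
  nf <- ncol(v)
  imin <- apply(v, 2L, which.min)
  per_frame <- data.frame(
    frame = seq_len(nf),
    frame_time = profile$frame_times,
    arclength_from_end = profile$bin_centers[imin],
    arclength_from_start = profile$total_length - profile$bin_centers[imin],
    min_radius = v[cbind(imin, seq_len(nf))]
  )
  bin_variance <- data.frame(
    bin_center = profile$bin_centers,
    variance = apply(v, 1L, function(x)
      if (length(x) > 1L) stats::var(x) else 0)
  )
  list(per_frame = per_frame, bin_variance = bin_variance)
}
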