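# Vessel-network geometry: the comb-shaped multi-bifurcation network, its
# lumen polygon, and the containment / exit predicates used by collision
# detection and the success metric.
#
# Coordinates are SI metres, origin at the centre of the inlet gate, +x
# downstream along the main channel, +y up. Everything is 2D (top-down view
# in the plane through the vessel centrelines).

#' Build a comb-shaped multi-bifurcation vessel network
#'
#' Constructs the testbed network: a straight horizontal main channel made of
#' `n_branches + 1` equal segments, with one downward branch vessel leaving
#' the main centreline at each of the `n_branches` junctions. The network has
#' a single inlet gate (at the origin) and `n_branches + 1` outlet gates: one
#' at the open end of each branch and one at the far end of the main channel.
#' The default geometry (4 branches, 1 mm wide and 5 mm long vessels) gives
#' the one-inlet / five-outlet layout used throughout.
#'
#' @param n_branches Number of downward branches (junctions). Default 4.
#' @param width Vessel width in metres (all vessels share it). Default 1e-3.
#' @param seg_length Vessel segment length in metres. Default 5e-3.
#' @param branch_angle Angle of the branches below the +x axis, in radians;
#'   `pi/2` (the default) points straight down. Must lie in (0, pi) so that
#'   branches leave the main channel downward.
#' @param goal_outlet Identifier of the goal outlet. Defaults to `"main_end"`,
#'   the outlet at the far end of the main channel (the hardest target: the
#'   swarm must pass every branch junction). Branch outlets are named
#'   `"branch_1"` ... `"branch_<n_branches>"`.
#'
#' @return An object of class `swarm_network`: a list with elements
#'   `segments` (data frame: id, x0, y0, x1, y1, width, role), `junctions`
#'   (list of `(node, segment_ids)`), `inlet_node`, `inlet_gate`, `outlets`
#'   (named list of 2x2 gate matrices, one row per gate endpoint),
#'   `goal_outlet`, `width` and `seg_length`.
#' @examples
#' net <- build_comb_network()
#' length(net$outlets)  # 5
#' @export
build_comb_network <- function(n_branches = 4L, width = 1e-3,
                               seg_length = 5e-3, branch_angle = pi / 2,
                               goal_outlet = "main_end") {
  if (n_branches < 1L) stop("invalid geometry: n_branches must be >= 1")
  if (width <= 0 || seg_length <= 0)
    stop("invalid geometry: width and seg_length must be positive")
  if (branch_angle <= 0 || branch_angle >= pi)
    stop("invalid geometry: branch_angle must lie in (0, pi) (downward)")

  n_main <- n_branches + 1L
  xj <- seg_length * seq_len(n_branches)           # junction x positions
  dir <- c(cos(-branch_angle), sin(-branch_angle)) # branch direction (down)

  seg <- data.frame(
    id = c(paste0("main_", seq_len(n_main)), paste0("branch_", seq_len(n_branches))),
    x0 = c(seg_length * (seq_len(n_main) - 1L), xj),
    y0 = c(rep(0, n_main), rep(0, n_branches)),
    x1 = c(seg_length * seq_len(n_main), xj + seg_length * dir[1]),
    y1 = c(rep(0, n_main), rep(seg_length * dir[2], n_branches)),
    width = width,
    role = c("inlet", rep("main", n_main - 1L), rep("branch", n_branches)),
    stringsAsFactors = FALSE
  )

  junctions <- lapply(seq_len(n_branches), function(j) {
    list(node = c(xj[j], 0),
         segment_ids = c(paste0("main_", j), paste0("main_", j + 1L),
                         paste0("branch_", j)))
  })

  # outlet gates: the open end of each terminal vessel, as a 2-point segment
  perp <- c(-dir[2], dir[1])   # unit perpendicular to the branch axis
  outlets <- list()
  for (j in seq_len(n_branches)) {
    end <- c(xj[j], 0) + seg_length * dir
    outlets[[paste0("branch_", j)]] <- rbind(end + (width / 2) * perp,
                                             end - (width / 2) * perp)
  }
  x_end <- seg_length * n_main
  outlets[["main_end"]] <- rbind(c(x_end, -width / 2), c(x_end, width / 2))

  if (!goal_outlet %in% names(outlets))
    stop("invalid geometry: goal_outlet must be one of ",
         paste(names(outlets), collapse = ", "))

  structure(list(
    segments = seg,
    junctions = junctions,
    inlet_node = c(0, 0),
    inlet_gate = rbind(c(0, -width / 2), c(0, width / 2)),
    outlets = outlets,
    goal_outlet = goal_outlet,
    width = width,
    seg_length = seg_length,
    branch_angle = branch_angle
  ), class = "swarm_network")
}

#' @export
print.swarm_network <- function(x, ...) {
  cat("<swarm_network> ", nrow(x$segments), " segments, ",
      length(x$outlets), " outlets (goal: ", x$goal_outlet, "), width ",
      format(x$width), " m\n", sep = "")
  invisible(x)
}

segment_lengths <- function(graph) {
  with(graph$segments, sqrt((x1 - x0)^2 + (y1 - y0)^2))
}

#' Realize a network as its navigable lumen polygon
#'
#' Converts a comb network to the closed polygon bounding its lumen: the
#' union of the per-segment rectangles (centreline +/- width/2) with junction
#' interiors filled. The boundary is returned counter-clockwise; the outlet
#' and inlet gates lie on the hull, closing it.
#'
#' @param graph A `swarm_network` built by [build_comb_network()].
#' @return An object of class `lumen_polygon`: a list with `boundary` (an
#'   n x 2 matrix of vertices, counter-clockwise, not repeated at the end)
#'   and `holes` (empty for comb networks).
#' @export
network_to_polygon <- function(graph) {
  stopifnot(inherits(graph, "swarm_network"))
  w <- graph$width
  L <- graph$seg_length
  theta <- graph$branch_angle
  n_branches <- length(graph$junctions)
  x_end <- L * (n_branches + 1L)
  dir <- c(cos(-theta), sin(-theta))
  perp <- c(-dir[2], dir[1])
  xj <- vapply(graph$junctions, function(j) j$node[1], numeric(1))

  # where the two branch side walls meet the bottom wall y = -w/2:
  # side wall through (xj +/- (w/2) perp) along dir, solve for y = -w/2
  t_plus  <- (w / 2 * perp[2] + w / 2) / (-dir[2])  # downstream side (+perp)
  t_minus <- (-w / 2 * perp[2] + w / 2) / (-dir[2]) # upstream side  (-perp)

  verts <- list(c(0, w / 2), c(x_end, w / 2), c(x_end, -w / 2))
  for (j in rev(seq_len(n_branches))) {
    root <- c(xj[j], 0)
    p_plus <- root + (w / 2) * perp + t_plus * dir    # on y = -w/2
    p_minus <- root - (w / 2) * perp + t_minus * dir  # on y = -w/2
    g_plus <- root + L * dir + (w / 2) * perp         # gate corners
    g_minus <- root + L * dir - (w / 2) * perp
    verts <- c(verts, list(p_plus, g_plus, g_minus, p_minus))
  }
  verts <- c(verts, list(c(0, -w / 2)))
  boundary <- do.call(rbind, verts)

  if (polygon_area(boundary) < 0) boundary <- boundary[rev(seq_len(nrow(boundary))), ]
  if (has_self_intersection(boundary))
    stop("invalid geometry: lumen boundary self-intersects ",
         "(branches too shallow or too close)")
  structure(list(boundary = boundary, holes = list()), class = "lumen_polygon")
}

#' @export
print.lumen_polygon <- function(x, ...) {
  cat("<lumen_polygon> ", nrow(x$boundary), " vertices, area ",
      format(polygon_area(x$boundary)), " m^2\n", sep = "")
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param boundary n x 2 matrix of vertices (not closed).
#' @return Signed area in m^2.
#' @export
polygon_area <- function(boundary) {
  x <- boundary[, 1]; y <- boundary[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# O(n^2) self-intersection scan; boundaries here have tens of vertices.
has_self_intersection <- function(boundary) {
  n <- nrow(boundary)
  segs <- cbind(boundary, rbind(boundary[-1, , drop = FALSE], boundary[1, , drop = FALSE]))
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    for (j in js) {
      hit <- cpp_gate_crossed(segs[i, 1], segs[i, 2], segs[i, 3], segs[i, 4],
                              matrix(segs[j, ], 1))
      if (!is.na(hit[1])) return(TRUE)
    }
  }
  FALSE
}

#' Test whether points lie inside the lumen
#'
#' Boundary-inclusive even-odd point-in-polygon test: points on the boundary
#' count as inside, so particles resting on a wall remain valid.
#'
#' @param polygon A `lumen_polygon`.
#' @param p A length-2 point or an n x 2 matrix of points (metres).
#' @return A logical vector, one entry per point.
#' @export
point_in_lumen <- function(polygon, p) {
  p <- as_points(p)
  cpp_point_in_polygon(p[, 1], p[, 2], polygon$boundary)
}

as_points <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 2, byrow = TRUE) else as.matrix(p)
}

#' Closest boundary point and inward normal
#'
#' For each query point, returns the closest point on the lumen boundary and
#' the unit normal of the corresponding edge oriented into the lumen. Used by
#' the collision model and by wall-contact diagnostics.
#'
#' @param polygon A `lumen_polygon`.
#' @param p A length-2 point or an n x 2 matrix (metres).
#' @return A list with `foot` (n x 2), `normal` (n x 2, unit inward normals)
#'   and `distance` (length n).
#' @export
nearest_boundary <- function(polygon, p) {
  p <- as_points(p)
  res <- cpp_nearest_boundary(p[, 1], p[, 2], polygon$boundary)
  res$distance <- sqrt(rowSums((p - res$foot)^2))
  res
}

#' Which outlet gate (if any) does a particle step cross?
#'
#' Tests the directed step `p_prev -> p_new` against every outlet gate of the
#' network. A particle whose step crosses a gate has exited through that
#' outlet and is thereafter inactive.
#'
#' @param graph A `swarm_network`.
#' @param p_prev,p_new Length-2 points, or n x 2 matrices of steps (metres).
#' @return A character vector of outlet ids (`NA` where no gate is crossed).
#' @export
outlet_crossed <- function(graph, p_prev, p_new) {
  p0 <- as_points(p_prev); p1 <- as_points(p_new)
  idx <- cpp_gate_crossed(p0[, 1], p0[, 2], p1[, 1], p1[, 2],
                          gate_matrix(graph))
  names(graph$outlets)[idx]
}

# gates as an n x 4 matrix (x0, y0, x1, y1) in the order of graph$outlets
gate_matrix <- function(graph) {
  do.call(rbind, lapply(graph$outlets, function(g) c(g[1, ], g[2, ])))
}

#' Write / read a network geometry JSON file
#'
#' The schema stores explicit coordinates (metres) so that non-comb networks
#' can be supplied: `segments` (id, start, end, width, role), `outlets`
#' (id, gate as two points), `inlet_gate`, `inlet_node`, `goal_outlet`, and
#' optionally an explicit `boundary` vertex list overriding
#' [network_to_polygon()].
#'
#' @param graph A `swarm_network`.
#' @param path File path.
#' @return `write_network_json` returns `path` invisibly; `read_network_json`
#'   returns a `swarm_network`.
#' @export
write_network_json <- function(graph, path) {
  seg <- graph$segments
  obj <- list(
    schema = "microsteer-network/1",
    segments = lapply(seq_len(nrow(seg)), function(i) list(
      id = seg$id[i], start = c(seg$x0[i], seg$y0[i]),
      end = c(seg$x1[i], seg$y1[i]), width = seg$width[i], role = seg$role[i]
    )),
    junctions = lapply(graph$junctions, function(j)
      list(node = j$node, segment_ids = j$segment_ids)),
    inlet_node = graph$inlet_node,
    inlet_gate = list(graph$inlet_gate[1, ], graph$inlet_gate[2, ]),
    outlets = lapply(names(graph$outlets), function(id) list(
      id = id, gate = list(graph$outlets[[id]][1, ], graph$outlets[[id]][2, ])
    )),
    goal_outlet = graph$goal_outlet,
    width = graph$width,
    seg_length = graph$seg_length,
    branch_angle = graph$branch_angle
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "microsteer-network/1"))
    stop("unsupported network schema version: ", obj$schema)
  seg <- do.call(rbind, lapply(obj$segments, function(s) data.frame(
    id = s$id, x0 = s$start[[1]], y0 = s$start[[2]],
    x1 = s$end[[1]], y1 = s$end[[2]], width = s$width, role = s$role,
    stringsAsFactors = FALSE
  )))
  outlets <- list()
  for (o in obj$outlets)
    outlets[[o$id]] <- rbind(unlist(o$gate[[1]]), unlist(o$gate[[2]]))
  structure(list(
    segments = seg,
    junctions = lapply(obj$junctions, function(j)
      list(node = unlist(j$node), segment_ids = unlist(j$segment_ids))),
    inlet_node = unlist(obj$inlet_node),
    inlet_gate = rbind(unlist(obj$inlet_gate[[1]]), unlist(obj$inlet_gate[[2]])),
    outlets = outlets,
    goal_outlet = obj$goal_outlet,
    width = obj$width,
    seg_length = obj$seg_length,
    branch_angle = obj$branch_angle
  ), class = "swarm_network")
}
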