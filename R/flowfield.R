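# Hagen-Poiseuille network flow: an analytic stand-in for a finite-element
# CFD solve. Each vessel is a 2D slit channel with conductance per unit depth
# G = w^3 / (12 eta L); nodal pressures solve the linear mass-conservation
# system with all outlets at a common reference pressure and a prescribed
# inlet inflow. Velocity profiles across each vessel are parabolic (no-slip),
# and a regular-grid lookup table of point velocities is sampled at run time
# by exact nearest-neighbour search.

#' Flow-field configuration
#'
#' @param inlet_central_velocity Centreline velocity at the inlet, m/s. The
#'   study range is 0.005 to 0.06 m/s; default 0.005.
#' @param viscosity Dynamic viscosity, Pa s. Default 1e-3 (water).
#' @param fluid Descriptive fluid name.
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(inlet_central_velocity = 0.005, viscosity = 1e-3,
                        fluid = "water") {
  if (inlet_central_velocity <= 0) stop("inlet_central_velocity must be > 0")
  if (viscosity <= 0) stop("viscosity must be > 0")
  structure(list(inlet_central_velocity = inlet_central_velocity,
                 viscosity = viscosity, fluid = fluid),
            class = "flow_config")
}

# map segment endpoints to node ids, merging coincident points (1e-9 m)
node_key <- function(x, y) paste(round(x * 1e9), round(y * 1e9))

#' Solve the hydraulic network
#'
#' Computes per-segment volumetric flow per unit depth `Q` (m^2/s, signed
#' along start -> end), centreline velocity `v_c = (3/2) Q / w`, and nodal
#' pressures (arbitrary units, outlets at 0). The inlet inflow is
#' `Q_in = (2/3) v_c,inlet w`, the flux of a parabolic slit profile with the
#' configured centreline velocity.
#'
#' @param graph A `swarm_network`.
#' @param config A `flow_config`.
#' @return An object of class `hydraulic_solution`: list with `segments`
#'   (data frame: id, Q, v_c, conductance), `pressures` (named vector),
#'   `Q_in`, and the `config`.
#' @export
solve_network_flow <- function(graph, config) {
  stopifnot(inherits(graph, "swarm_network"), inherits(config, "flow_config"))
  seg <- graph$segments
  len <- segment_lengths(graph)
  G <- seg$width^3 / (12 * config$viscosity * len)

  k0 <- node_key(seg$x0, seg$y0)
  k1 <- node_key(seg$x1, seg$y1)
  keys <- unique(c(k0, k1))
  id0 <- match(k0, keys)
  id1 <- match(k1, keys)
  n <- length(keys)

  # classify nodes: the inlet node and the outlet (gate-end) nodes
  inlet_id <- match(node_key(graph$inlet_node[1], graph$inlet_node[2]), keys)
  outlet_ids <- vapply(graph$outlets, function(g) {
    mid <- colMeans(g)
    match(node_key(mid[1], mid[2]), keys)
  }, integer(1))
  if (is.na(inlet_id) || anyNA(outlet_ids))
    stop("flow solver: inlet/outlet nodes do not coincide with segment ends")

  # weighted graph Laplacian
  A <- matrix(0, n, n)
  for (i in seq_len(nrow(seg))) {
    a <- id0[i]; b <- id1[i]
    A[a, a] <- A[a, a] + G[i]; A[b, b] <- A[b, b] + G[i]
    A[a, b] <- A[a, b] - G[i]; A[b, a] <- A[b, a] - G[i]
  }
  Q_in <- (2 / 3) * config$inlet_central_velocity * graph$segments$width[1]
  rhs <- numeric(n)
  rhs[inlet_id] <- Q_in
  # Dirichlet P = 0 at outlets
  for (o in outlet_ids) {
    A[o, ] <- 0
    A[o, o] <- 1
    rhs[o] <- 0
  }
  P <- tryCatch(solve(A, rhs),
                error = function(e) stop("flow solver: singular system ",
                                         "(disconnected network?)"))
  Q <- G * (P[id0] - P[id1])
  v_c <- (3 / 2) * Q / seg$width
  structure(list(
    segments = data.frame(id = seg$id, Q = Q, v_c = v_c, conductance = G,
                          stringsAsFactors = FALSE),
    pressures = stats::setNames(P, keys),
    Q_in = Q_in,
    config = config
  ), class = "hydraulic_solution")
}

#' @export
print.hydraulic_solution <- function(x, ...) {
  cat("<hydraulic_solution> Q_in =", format(x$Q_in), "m^2/s\n")
  print(x$segments, ...)
  invisible(x)
}

# unit axis and transverse offset of p relative to a segment row
segment_frame <- function(seg_row, p) {
  a <- c(seg_row$x0, seg_row$y0)
  b <- c(seg_row$x1, seg_row$y1)
  axis <- (b - a) / sqrt(sum((b - a)^2))
  rel <- c(p[1] - a[1], p[2] - a[2])
  list(axis = axis,
       s = -axis[2] * rel[1] + axis[1] * rel[2],   # signed transverse offset
       u = axis[1] * rel[1] + axis[2] * rel[2])    # along-axis coordinate
}

#' Local parabolic velocity within a vessel segment
#'
#' Velocity is directed along the segment axis with the plane-Poiseuille
#' profile `v_c (1 - (2 s / w)^2)`, where `s` is the signed transverse offset
#' from the centreline; it vanishes at the walls (`|s| = w/2`).
#'
#' @param solution A `hydraulic_solution`.
#' @param graph The `swarm_network` the solution was computed on.
#' @param segment_id Segment identifier.
#' @param p Length-2 point inside the segment rectangle (metres).
#' @return Length-2 velocity vector, m/s.
#' @export
local_velocity <- function(solution, graph, segment_id, p) {
  i <- match(segment_id, graph$segments$id)
  if (is.na(i)) stop("unknown segment id: ", segment_id)
  row <- graph$segments[i, ]
  fr <- segment_frame(row, p)
  len <- sqrt((row$x1 - row$x0)^2 + (row$y1 - row$y0)^2)
  if (abs(fr$s) > row$width / 2 + 1e-12 || fr$u < -1e-12 || fr$u > len + 1e-12)
    stop("point lies outside segment ", segment_id)
  v_c <- solution$segments$v_c[match(segment_id, solution$segments$id)]
  mag <- v_c * (1 - (2 * fr$s / row$width)^2)
  mag * fr$axis
}

#' Build the flow lookup table
#'
#' Samples a regular grid over the lumen bounding box, keeps the in-lumen
#' nodes, and attaches the local parabolic velocity of the nearest vessel
#' centreline (which at junction interiors assigns the velocity of the
#' closest centreline's segment). The default spacing of 75 um yields at
#' least 7000 table points for the default one-inlet / five-outlet network.
#'
#' @param graph A `swarm_network`.
#' @param solution Its `hydraulic_solution`.
#' @param polygon Optional `lumen_polygon` (rebuilt from `graph` if missing).
#' @param spacing Grid spacing in metres. Default 7.5e-5.
#' @return An object of class `flow_lookup`: list with `points` (n x 2),
#'   `velocities` (n x 2), `spacing`, and the grid index (`x0`, `y0`, `nx`,
#'   `ny`, `cell`) used for fast exact nearest-neighbour sampling.
#' @export
build_lookup_table <- function(graph, solution, polygon = NULL,
                               spacing = 7.5e-5) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (is.null(polygon)) polygon <- network_to_polygon(graph)
  bnd <- polygon$boundary
  x0 <- min(bnd[, 1]); y0 <- min(bnd[, 2])
  nx <- floor((max(bnd[, 1]) - x0) / spacing + 1e-9) + 1L
  ny <- floor((max(bnd[, 2]) - y0) / spacing + 1e-9) + 1L
  gx <- x0 + spacing * (seq_len(nx) - 1L)
  gy <- y0 + spacing * (seq_len(ny) - 1L)
  pts <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  keep <- point_in_lumen(polygon, pts)
  pts <- pts[keep, , drop = FALSE]

  vel <- velocity_at_points(graph, solution, pts)

  cell <- rep(-1L, nx * ny)
  cell[which(keep) - 1L + 1L] <- seq_len(nrow(pts)) - 1L  # 0-based point ids
  structure(list(points = pts, velocities = vel, spacing = spacing,
                 x0 = x0, y0 = y0, nx = nx, ny = ny, cell = as.integer(cell),
                 boundary = bnd),
            class = "flow_lookup")
}

# nearest-centreline velocity assignment, vectorised over points
velocity_at_points <- function(graph, solution, pts) {
  seg <- graph$segments
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_i <- rep(1L, n)
  for (i in seq_len(nrow(seg))) {
    a <- c(seg$x0[i], seg$y0[i]); b <- c(seg$x1[i], seg$y1[i])
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_i[upd] <- i
  }
  vel <- matrix(0, n, 2)
  for (i in unique(best_i)) {
    sel <- best_i == i
    row <- seg[i, ]
    axis <- c(row$x1 - row$x0, row$y1 - row$y0)
    axis <- axis / sqrt(sum(axis^2))
    s <- -axis[2] * (pts[sel, 1] - row$x0) + axis[1] * (pts[sel, 2] - row$y0)
    v_c <- solution$segments$v_c[i]
    mag <- v_c * pmax(0, 1 - (2 * s / row$width)^2)
    vel[sel, 1] <- mag * axis[1]
    vel[sel, 2] <- mag * axis[2]
  }
  vel
}

#' @export
print.flow_lookup <- function(x, ...) {
  cat("<flow_lookup> ", nrow(x$points), " points, spacing ",
      format(x$spacing), " m\n", sep = "")
  invisible(x)
}

#' Sample the flow lookup table
#'
#' Returns the velocity of the Euclidean-nearest table point for each query,
#' and the zero vector for queries outside the lumen. The regular-grid index
#' makes the search exact and O(1) for in-lumen queries.
#'
#' @param table A `flow_lookup`.
#' @param p Length-2 point or n x 2 matrix (metres).
#' @return n x 2 matrix of velocities, m/s.
#' @export
sample_flow <- function(table, p) {
  if (nrow(table$points) == 0) stop("empty flow lookup table")
  p <- as_points(p)
  cpp_sample_flow(p[, 1], p[, 2], table$x0, table$y0, table$spacing,
                  table$nx, table$ny, table$cell, table$velocities,
                  table$boundary)
}

#' Write / read a flow lookup table as CSV
#'
#' The format follows the convention of CFD point-export files: one header
#' row with columns `x_m, y_m, u_m_per_s, v_m_per_s`. Values are written with
#' 15 significant digits so a round trip preserves them to at least 12.
#' Extra trailing columns (as found in externally exported tables) are
#' ignored with a warning; non-numeric cells raise an error naming the line.
#'
#' @param table A `flow_lookup`.
#' @param path CSV file path.
#' @param graph,polygon Network and lumen the table belongs to; required by
#'   `read_flow_csv` to rebuild the sampling index (the grid is inferred from
#'   the point coordinates).
#' @return `write_flow_csv` returns `path` invisibly; `read_flow_csv` a
#'   `flow_lookup`.
#' @export
write_flow_csv <- function(table, path) {
  df <- data.frame(x_m = format(table$points[, 1], digits = 15),
                   y_m = format(table$points[, 2], digits = 15),
                   u_m_per_s = format(table$velocities[, 1], digits = 15),
                   v_m_per_s = format(table$velocities[, 2], digits = 15))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path, polygon) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 strip.white = TRUE)
  need <- c("x_m", "y_m", "u_m_per_s", "v_m_per_s")
  if (!all(need %in% names(df)))
    stop("flow CSV is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra) > 0)
    warning("flow CSV: ignoring extra columns ", paste(extra, collapse = ", "))
  vals <- lapply(need, function(cn) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad) > 0)
      stop("flow CSV parse error: non-numeric value in column '", cn,
           "' at line ", bad[1] + 1L)  # +1 for the header row
    v
  })
  pts <- cbind(vals[[1]], vals[[2]])
  vel <- cbind(vals[[3]], vals[[4]])
  lookup_from_points(pts, vel, polygon)
}

# rebuild the regular-grid index from raw table points (spacing inferred as
# the smallest positive coordinate gap)
lookup_from_points <- function(pts, vel, polygon) {
  ux <- sort(unique(pts[, 1])); uy <- sort(unique(pts[, 2]))
  gaps <- c(diff(ux), diff(uy))
  gaps <- gaps[gaps > 1e-15]
  spacing <- if (length(gaps) > 0) min(gaps) else 1
  x0 <- min(pts[, 1]); y0 <- min(pts[, 2])
  ix <- as.integer(round((pts[, 1] - x0) / spacing))
  iy <- as.integer(round((pts[, 2] - y0) / spacing))
  if (max(abs(pts[, 1] - (x0 + ix * spacing))) > 1e-9 ||
      max(abs(pts[, 2] - (y0 + iy * spacing))) > 1e-9)
    stop("flow CSV points do not lie on a regular grid")
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  cell <- rep(-1L, nx * ny)
  cell[ix + iy * nx + 1L] <- seq_len(nrow(pts)) - 1L
  structure(list(points = pts, velocities = vel, spacing = spacing,
                 x0 = x0, y0 = y0, nx = nx, ny = ny, cell = cell,
                 boundary = polygon$boundary),
            class = "flow_lookup")
}
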