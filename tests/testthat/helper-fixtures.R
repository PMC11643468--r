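# Shared fixtures and independent oracle implementations. The oracles are
# deliberately written with different algorithms from the package code they
# check (ray casting vs. the compiled even-odd test, linear scans vs. the
# grid index, ladder recursion vs. the Laplacian solve).

default_network <- function() build_comb_network()

default_polygon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- network_to_polygon(build_comb_network())
    cache
  }
})

# a single straight 5 mm x 1 mm channel as a plain rectangle polygon
rect_polygon <- function(x0 = 0, y0 = -5e-4, x1 = 5e-3, y1 = 5e-4) {
  structure(list(boundary = rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
                 holes = list()),
            class = "lumen_polygon")
}

# --- oracle: ray-casting point-in-polygon (horizontal ray, edge-inclusive) --
oracle_pip <- function(boundary, p, eps = 1e-12) {
  n <- nrow(boundary)
  crossings <- 0
  for (k in seq_len(n)) {
    a <- boundary[k, ]
    b <- boundary[if (k == n) 1 else k + 1, ]
    # on-edge test via the triangle area and projection
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    if (sqrt(sum((p - (a + t * ab))^2)) <= eps) return(TRUE)
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      x_int <- a[1] + (p[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (x_int > p[1]) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# --- oracle: brute-force nearest table point -------------------------------
oracle_nearest_velocity <- function(table, p) {
  d2 <- (table$points[, 1] - p[1])^2 + (table$points[, 2] - p[2])^2
  table$velocities[which.min(d2), ]
}

# --- oracle: comb-network flows by ladder recursion ------------------------
# Equal-conductance comb with n branches: walking backwards from the far end
# with unit pressure at the last junction gives integer flow ratios; scaled
# so the inlet segment carries Q_in. Returns flows in segment order
# main_1..main_{n+1}, branch_1..branch_n.
oracle_comb_flows <- function(n_branches, Q_in) {
  p <- numeric(n_branches)        # junction pressures / r, far to near
  main <- numeric(n_branches + 1) # main-segment flows, far to near
  main[1] <- 1                    # last main segment (to the end outlet)
  p[1] <- 1                       # last junction pressure
  for (j in seq_len(n_branches - 1)) {
    main[j + 1] <- p[j] + main[j]      # feed = branch (=p) + downstream main
    p[j + 1] <- p[j] + main[j + 1]     # pressure one junction upstream
  }
  main[n_branches + 1] <- p[n_branches] + main[n_branches]
  branch <- p
  total <- main[n_branches + 1]
  list(main = rev(main) * Q_in / total,
       branch = rev(branch) * Q_in / total)
}

# random in-lumen points, rejection-sampled from the bounding box
random_lumen_points <- function(polygon, n, seed = 42) {
  bnd <- polygon$boundary
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    cand <- cbind(runif(2 * n, min(bnd[, 1]), max(bnd[, 1])),
                  runif(2 * n, min(bnd[, 2]), max(bnd[, 2])))
    keep <- point_in_lumen(polygon, cand)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}

# flow table for the default network at a given inlet velocity
flow_table_at <- function(graph, polygon, v_in, spacing = 7.5e-5) {
  build_lookup_table(graph, solve_network_flow(graph, flow_config(v_in)),
                     polygon, spacing = spacing)
}

# uniform synthetic flow table covering a rectangle polygon (for dynamics
# tests where an analytically known field is needed)
uniform_flow_table <- function(polygon, u, v, spacing = 1e-4) {
  bnd <- polygon$boundary
  x0 <- min(bnd[, 1]); y0 <- min(bnd[, 2])
  nx <- floor((max(bnd[, 1]) - x0) / spacing + 1e-9) + 1
  ny <- floor((max(bnd[, 2]) - y0) / spacing + 1e-9) + 1
  gx <- x0 + spacing * (seq_len(nx) - 1)
  gy <- y0 + spacing * (seq_len(ny) - 1)
  pts <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  keep <- point_in_lumen(polygon, pts)
  pts <- pts[keep, , drop = FALSE]
  cell <- rep(-1L, nx * ny)
  cell[which(keep)] <- seq_len(nrow(pts)) - 1L
  structure(list(points = pts,
                 velocities = cbind(rep(u, nrow(pts)), rep(v, nrow(pts))),
                 spacing = spacing, x0 = x0, y0 = y0,
                 nx = as.integer(nx), ny = as.integer(ny),
                 cell = as.integer(cell), boundary = bnd),
            class = "flow_lookup")
}
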