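# Hydraulic network solve, parabolic profiles, lookup table and sampling.

test_that("a single straight channel carries the inlet velocity throughout", {
  net <- structure(list(
    segments = data.frame(id = "main_1", x0 = 0, y0 = 0, x1 = 5e-3, y1 = 0,
                          width = 1e-3, role = "inlet",
                          stringsAsFactors = FALSE),
    junctions = list(),
    inlet_node = c(0, 0),
    inlet_gate = rbind(c(0, -5e-4), c(0, 5e-4)),
    outlets = list(main_end = rbind(c(5e-3, -5e-4), c(5e-3, 5e-4))),
    goal_outlet = "main_end", width = 1e-3, seg_length = 5e-3,
    branch_angle = pi / 2), class = "swarm_network")
  sol <- solve_network_flow(net, flow_config(0.02))
  expect_equal(sol$segments$v_c, 0.02, tolerance = 1e-12)
  expect_equal(sol$segments$Q, (2 / 3) * 0.02 * 1e-3, tolerance = 1e-12)
})

test_that("a symmetric Y splits the inlet flow in half", {
  # one feed segment, two identical branches to outlets
  net <- structure(list(
    segments = data.frame(
      id = c("feed", "up", "down"),
      x0 = c(0, 5e-3, 5e-3), y0 = c(0, 0, 0),
      x1 = c(5e-3, 10e-3, 10e-3), y1 = c(0, 4e-3, -4e-3),
      width = 1e-3, role = c("inlet", "branch", "branch"),
      stringsAsFactors = FALSE),
    junctions = list(list(node = c(5e-3, 0),
                          segment_ids = c("feed", "up", "down"))),
    inlet_node = c(0, 0),
    inlet_gate = rbind(c(0, -5e-4), c(0, 5e-4)),
    outlets = list(up = rbind(c(10e-3, 4e-3), c(10e-3, 4e-3)),
                   down = rbind(c(10e-3, -4e-3), c(10e-3, -4e-3))),
    goal_outlet = "up", width = 1e-3, seg_length = 5e-3,
    branch_angle = pi / 2), class = "swarm_network")
  sol <- solve_network_flow(net, flow_config(0.01))
  Q_in <- sol$Q_in
  expect_equal(sol$segments$Q[sol$segments$id == "feed"], Q_in,
               tolerance = 1e-12)
  expect_equal(sol$segments$Q[sol$segments$id == "up"], Q_in / 2,
               tolerance = 1e-12)
  expect_equal(sol$segments$Q[sol$segments$id == "down"], Q_in / 2,
               tolerance = 1e-12)
})

test_that("comb flows match the independent ladder-recursion oracle", {
  net <- default_network()
  sol <- solve_network_flow(net, flow_config(0.02))
  oracle <- oracle_comb_flows(4, sol$Q_in)
  got_main <- sol$segments$Q[match(paste0("main_", 1:5), sol$segments$id)]
  got_branch <- sol$segments$Q[match(paste0("branch_", 1:4), sol$segments$id)]
  expect_equal(got_main, oracle$main, tolerance = 1e-10)
  expect_equal(got_branch, oracle$branch, tolerance = 1e-10)
})

test_that("flow is conserved at every junction", {
  net <- default_network()
  sol <- solve_network_flow(net, flow_config(0.06))
  seg <- net$segments
  for (j in net$junctions) {
    net_flux <- 0
    for (sid in j$segment_ids) {
      i <- match(sid, seg$id)
      sgn <- if (abs(seg$x0[i] - j$node[1]) + abs(seg$y0[i] - j$node[2]) < 1e-12)
        -1 else +1  # outgoing segments subtract
      net_flux <- net_flux + sgn * sol$segments$Q[i]
    }
    expect_lt(abs(net_flux), 1e-12 * abs(sol$Q_in))
  }
})

test_that("solver output is invariant under segment reorder and translation", {
  net <- default_network()
  sol <- solve_network_flow(net, flow_config(0.02))

  perm <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  net2 <- net
  net2$segments <- net$segments[perm, ]
  sol2 <- solve_network_flow(net2, flow_config(0.02))
  expect_equal(sol2$segments$Q[match(net$segments$id, sol2$segments$id)],
               sol$segments$Q, tolerance = 1e-12)

  shift <- c(0.1, -0.2)
  net3 <- net
  net3$segments$x0 <- net$segments$x0 + shift[1]
  net3$segments$x1 <- net$segments$x1 + shift[1]
  net3$segments$y0 <- net$segments$y0 + shift[2]
  net3$segments$y1 <- net$segments$y1 + shift[2]
  net3$inlet_node <- net$inlet_node + shift
  net3$outlets <- lapply(net$outlets, function(g) sweep(g, 2, -shift))
  sol3 <- solve_network_flow(net3, flow_config(0.02))
  expect_equal(sol3$segments$Q, sol$segments$Q, tolerance = 1e-12)
})

test_that("local parabolic profile: centreline max, no-slip walls, 2/3 mean", {
  net <- default_network()
  sol <- solve_network_flow(net, flow_config(0.02))
  v_c <- sol$segments$v_c[1]
  centre <- local_velocity(sol, net, "main_1", c(2.5e-3, 0))
  expect_equal(centre, c(v_c, 0), tolerance = 1e-12)
  wall <- local_velocity(sol, net, "main_1", c(2.5e-3, 5e-4))
  expect_equal(wall, c(0, 0), tolerance = 1e-12)
  # transverse average = (2/3) v_c and monotone decay toward the walls
  s <- seq(-5e-4, 5e-4, length.out = 20001)
  mags <- vapply(s, function(si)
    local_velocity(sol, net, "main_1", c(2.5e-3, si))[1], numeric(1))
  expect_equal(mean(mags), (2 / 3) * v_c, tolerance = 1e-4)
  upper <- mags[s >= 0]
  expect_true(all(diff(upper) <= 1e-15))
  expect_error(local_velocity(sol, net, "main_1", c(2.5e-3, 2e-3)),
               "outside segment")
})

test_that("lookup table covers the lumen densely enough", {
  net <- default_network()
  poly <- default_polygon()
  tab <- flow_table_at(net, poly, 0.02)
  expect_gte(nrow(tab$points), 7000)
  expect_true(all(point_in_lumen(poly, tab$points)))

  # single 5 mm x 1 mm channel at 0.05 mm spacing: 101 x 21 nodes
  net1 <- structure(list(
    segments = data.frame(id = "main_1", x0 = 0, y0 = 0, x1 = 5e-3, y1 = 0,
                          width = 1e-3, role = "inlet",
                          stringsAsFactors = FALSE),
    junctions = list(), inlet_node = c(0, 0),
    inlet_gate = rbind(c(0, -5e-4), c(0, 5e-4)),
    outlets = list(main_end = rbind(c(5e-3, -5e-4), c(5e-3, 5e-4))),
    goal_outlet = "main_end", width = 1e-3, seg_length = 5e-3,
    branch_angle = pi / 2), class = "swarm_network")
  sol1 <- solve_network_flow(net1, flow_config(0.02))
  tab1 <- build_lookup_table(net1, sol1, rect_polygon(), spacing = 5e-5)
  expect_identical(nrow(tab1$points), 101L * 21L)
})

test_that("nearest-neighbour sampling equals the brute-force scan", {
  net <- default_network()
  poly <- default_polygon()
  tab <- flow_table_at(net, poly, 0.02, spacing = 2e-4)
  pts <- random_lumen_points(poly, 1000, seed = 3)
  got <- sample_flow(tab, pts)
  for (i in seq_len(nrow(pts))) {
    expect_equal(got[i, ], oracle_nearest_velocity(tab, pts[i, ]),
                 tolerance = 1e-15)
  }
  # a query on a table point returns exactly that point's velocity
  expect_equal(sample_flow(tab, tab$points[10, ]), tab$velocities[10, ,
               drop = FALSE], ignore_attr = TRUE)
  # outside the lumen: zero vector
  expect_equal(drop(sample_flow(tab, c(-1e-3, 0))), c(0, 0))
  expect_equal(drop(sample_flow(tab, c(1e-2, 2e-3))), c(0, 0))
})

test_that("flow CSV round trip preserves values and rejects bad input", {
  net <- default_network()
  poly <- default_polygon()
  tab <- flow_table_at(net, poly, 0.02, spacing = 5e-4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(tab, path)
  back <- read_flow_csv(path, poly)
  expect_equal(back$points, tab$points, tolerance = 1e-12)
  expect_equal(back$velocities, tab$velocities, tolerance = 1e-12)
  # sampling through the reread table agrees
  pts <- random_lumen_points(poly, 50, seed = 5)
  expect_equal(sample_flow(back, pts), sample_flow(tab, pts),
               tolerance = 1e-12)

  # non-numeric cell: parse error naming the line
  lines <- readLines(path)
  lines[3] <- sub("^[-0-9.e]+", "bogus", lines[3])
  writeLines(lines, path)
  expect_error(read_flow_csv(path, poly), "line 3")

  # extra trailing columns are ignored with a warning
  write_flow_csv(tab, path)
  lines <- readLines(path)
  lines[1] <- paste0(lines[1], ",T_K")
  lines[-1] <- paste0(lines[-1], ",293.15")
  writeLines(lines, path)
  expect_warning(back2 <- read_flow_csv(path, poly), "extra columns")
  expect_equal(back2$velocities, tab$velocities, tolerance = 1e-12)
})
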