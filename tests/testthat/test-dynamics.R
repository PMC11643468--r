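# Two-rate loop timing, semi-static kinematics, collisions, seeding and
# run-level conservation / determinism properties.

test_that("loop timing: 0.05 s major period splits into 25 steps of 0.002 s", {
  cfg <- sim_config()
  expect_equal(cfg$dt_minor, 0.002, tolerance = 1e-15)
  expect_equal(cfg$dt_minor * cfg$minors_per_major, cfg$major_period,
               tolerance = 1e-15)
})

test_that("semi-static velocity balances drag against the applied force", {
  # force-free particles advect with the fluid
  expect_equal(semi_static_velocity(c(0, 0), c(0.01, -0.002), 1e-3, 75e-9),
               c(0.01, -0.002), tolerance = 1e-15)
  # reference magnitude: full-gradient force on the default chain in still
  # fluid moves it at about 1.82 mm/s
  p <- magnetic_params()
  F <- magnetic_force(p, limit_gradient(c(1, 0), 1000))
  v <- semi_static_velocity(F, c(0, 0), 1e-3, 75e-9)
  expect_equal(signif(sqrt(sum(v^2)), 3), 1.82e-3)
  # doubling the viscosity halves the force-driven component
  v2 <- semi_static_velocity(F, c(0, 0), 2e-3, 75e-9)
  expect_equal(v2, v / 2, tolerance = 1e-15)
})

test_that("force-free particles in uniform flow translate by u*dt per step", {
  rect <- rect_polygon()
  tab <- uniform_flow_table(rect, u = 1e-3, v = 0)
  net <- build_comb_network(n_branches = 1L)  # graph only supplies gates
  cfg <- sim_config(N = 5L, gradient_limit = 500)
  state <- structure(list(
    positions = cbind(seq(1e-3, 2e-3, length.out = 5), rep(0, 5)),
    velocities = matrix(0, 5, 2),
    status = rep("active", 5),
    exit_outlet = rep(NA_character_, 5),
    exit_time = rep(NA_real_, 5), t = 0), class = "swarm_state")
  out <- minor_step(state, limit_gradient(c(0, 0), 500), tab, rect, net, cfg)
  expect_equal(out$positions[, 1], state$positions[, 1] + 1e-3 * 0.002,
               tolerance = 1e-15)
  expect_equal(out$positions[, 2], state$positions[, 2], tolerance = 1e-15)
  expect_equal(out$t, 0.002, tolerance = 1e-15)
})

test_that("25 minor steps advance the clock by exactly one major period", {
  net <- default_network()
  poly <- default_polygon()
  tab <- flow_table_at(net, poly, 0.02, spacing = 2e-4)
  cfg <- sim_config(N = 10L, rng_seed = 2L)
  state <- seed_particles(seed_spec(), 10L, 2L, poly)
  res <- major_step(state, constant_policy(c(0, 0)), tab, poly, net, cfg)
  expect_equal(res$state$t, 0.05, tolerance = 1e-15)
  expect_equal(res$record$t, 0)
  expect_equal(res$record$gradient, c(0, 0))
})

test_that("a particle one step from the goal gate exits with the goal id", {
  net <- default_network()
  poly <- default_polygon()
  tab <- flow_table_at(net, poly, 0.02, spacing = 2e-4)
  cfg <- sim_config(N = 1L, gradient_limit = 1000)
  state <- structure(list(
    positions = matrix(c(24.999e-3, 0), 1), velocities = matrix(0, 1, 2),
    status = "active", exit_outlet = NA_character_, exit_time = NA_real_,
    t = 0), class = "swarm_state")
  out <- minor_step(state, limit_gradient(c(1, 0), 1000), tab, poly, net, cfg)
  expect_identical(out$status, "exited")
  expect_identical(out$exit_outlet, "main_end")
  expect_equal(out$exit_time, 0.002, tolerance = 1e-15)
})

test_that("wall reflection is specular and elastic at mu = 0", {
  rect <- rect_polygon()
  # incoming at 45 degrees onto the bottom wall y = -0.5 mm
  p_prev <- c(2.5e-3, -4.9e-4)
  p_prop <- c(2.51e-3, -5.2e-4)  # outside
  v <- c(1e-3, -1e-3)
  res <- resolve_collision(p_prev, p_prop, v, rect, mu = 0)
  expect_true(res$resolved)
  expect_equal(res$velocity, c(1e-3, 1e-3), tolerance = 1e-12)
  expect_equal(sqrt(sum(res$velocity^2)), sqrt(sum(v^2)),
               tolerance = 1e-12)  # elastic: speed preserved exactly
  expect_true(point_in_lumen(rect, res$position))
  # the reflected position mirrors the residual penetration (to within the
  # 1e-9 m bisection tolerance on the crossing point)
  expect_lt(abs(res$position[2] - (-5e-4 + 0.2e-4)), 5e-9)

  # mu = 1: tangential component removed, normal component still reflected
  res2 <- resolve_collision(p_prev, p_prop, v, rect, mu = 1)
  expect_equal(res2$velocity, c(0, 1e-3), tolerance = 1e-12)

  # partial friction scales only the tangential component
  res3 <- resolve_collision(p_prev, p_prop, v, rect, mu = 0.25)
  expect_equal(res3$velocity, c(0.75e-3, 1e-3), tolerance = 1e-12)
})

test_that("seeding is reproducible, inside the square, and split halves N", {
  poly <- default_polygon()
  s1 <- seed_particles(seed_spec(), 500L, 7L, poly)
  s2 <- seed_particles(seed_spec(), 500L, 7L, poly)
  expect_identical(s1$positions, s2$positions)
  expect_true(all(s1$status == "active"))
  expect_equal(s1$t, 0)
  sq <- seed_spec()
  expect_true(all(abs(s1$positions[, 1] - sq$clump_center[1]) <= sq$side / 2))
  expect_true(all(abs(s1$positions[, 2] - sq$clump_center[2]) <= sq$side / 2))
  expect_true(all(point_in_lumen(poly, s1$positions)))

  sp <- seed_particles(seed_spec("split"), 501L, 7L, poly)
  n_first <- sum(abs(sp$positions[, 1] - sq$clump_center[1]) <= sq$side / 2)
  expect_identical(n_first, 251L)  # ceiling(N/2) in the clump square
  expect_identical(nrow(sp$positions), 501L)

  # a square outside the lumen is rejected
  expect_error(
    seed_particles(seed_spec(clump_center = c(1e-3, 0.4e-3)), 10L, 1L, poly),
    "invalid seed")
  # a different seed gives different draws
  s3 <- seed_particles(seed_spec(), 500L, 8L, poly)
  expect_false(identical(s1$positions, s3$positions))
})

test_that("particle count is conserved and actives stay inside the lumen", {
  net <- default_network()
  poly <- default_polygon()
  tab <- flow_table_at(net, poly, 0.03, spacing = 2e-4)
  cfg <- sim_config(N = 80L, gradient_limit = 300, rng_seed = 5L,
                    max_sim_time = 3)
  log <- run_simulation(cfg, net, tab, waypoint_autopilot(net),
                        polygon = poly)
  oc <- log$outcomes
  expect_identical(nrow(oc), 80L)
  tab_status <- table(factor(oc$status, c("active", "exited", "stuck")))
  expect_identical(sum(tab_status), 80L)
  expect_true(all(!is.na(oc$exit_outlet[oc$status == "exited"])))
  expect_true(all(is.na(oc$exit_outlet[oc$status != "exited"])))
  # active survivors are inside the lumen (within the bisection tolerance)
  act <- log$final_state$positions[log$final_state$status == "active", ,
                                   drop = FALSE]
  if (nrow(act) > 0) expect_true(all(point_in_lumen(poly, act)))
  # per-major-step record bookkeeping
  expect_equal(length(log$records), round(log$final_state$t / 0.05))
})

test_that("advection alone never pushes particles through the side walls", {
  # parabolic flow is wall-parallel in a straight channel
  net1 <- structure(list(
    segments = data.frame(id = "main_1", x0 = 0, y0 = 0, x1 = 5e-3, y1 = 0,
                          width = 1e-3, role = "inlet",
                          stringsAsFactors = FALSE),
    junctions = list(), inlet_node = c(0, 0),
    inlet_gate = rbind(c(0, -5e-4), c(0, 5e-4)),
    outlets = list(main_end = rbind(c(5e-3, -5e-4), c(5e-3, 5e-4))),
    goal_outlet = "main_end", width = 1e-3, seg_length = 5e-3,
    branch_angle = pi / 2), class = "swarm_network")
  rect <- rect_polygon()
  sol <- solve_network_flow(net1, flow_config(0.05))
  tab <- build_lookup_table(net1, sol, rect, spacing = 5e-5)
  cfg <- sim_config(N = 50L)
  set.seed(9)
  y0 <- runif(50, -4.9e-4, 4.9e-4)
  state <- structure(list(
    positions = cbind(rep(1e-4, 50), y0), velocities = matrix(0, 50, 2),
    status = rep("active", 50), exit_outlet = rep(NA_character_, 50),
    exit_time = rep(NA_real_, 50), t = 0), class = "swarm_state")
  out <- minor_step(state, limit_gradient(c(0, 0)), tab, rect, net1, cfg,
                    n_steps = 200L)
  moving <- out$status == "active"
  expect_true(all(out$positions[moving, 2] == y0[moving]))
  expect_true(all(abs(out$positions[, 2]) <= 5e-4 + 1e-9))
})

test_that("halving the timestep changes trajectories only at first order", {
  net1 <- structure(list(
    segments = data.frame(id = "main_1", x0 = 0, y0 = 0, x1 = 50e-3, y1 = 0,
                          width = 1e-3, role = "inlet",
                          stringsAsFactors = FALSE),
    junctions = list(), inlet_node = c(0, 0),
    inlet_gate = rbind(c(0, -5e-4), c(0, 5e-4)),
    outlets = list(main_end = rbind(c(50e-3, -5e-4), c(50e-3, 5e-4))),
    goal_outlet = "main_end", width = 1e-3, seg_length = 50e-3,
    branch_angle = pi / 2), class = "swarm_network")
  rect <- rect_polygon(0, -5e-4, 50e-3, 5e-4)
  sol <- solve_network_flow(net1, flow_config(0.02))
  tab <- build_lookup_table(net1, sol, rect, spacing = 2e-5)
  start <- c(1e-3, -2e-4)
  run_with_dt <- function(dt, n) {
    cfg <- sim_config(major_period = dt * 25, N = 1L, gradient_limit = 200)
    state <- structure(list(
      positions = matrix(start, 1), velocities = matrix(0, 1, 2),
      status = "active", exit_outlet = NA_character_,
      exit_time = NA_real_, t = 0), class = "swarm_state")
    out <- minor_step(state, limit_gradient(c(0.3, 0.4), 200), tab, rect,
                      net1, cfg, n_steps = n)
    out$positions[1, ]
  }
  p_dt <- run_with_dt(0.002, 250L)     # 0.5 s of simulated time
  p_half <- run_with_dt(0.001, 500L)
  # both integrate the same smooth field; the gap shrinks with dt
  expect_lt(sqrt(sum((p_dt - p_half)^2)), 5e-5)
  p_quarter <- run_with_dt(5e-4, 1000L)
  expect_lt(sqrt(sum((p_half - p_quarter)^2)),
            sqrt(sum((p_dt - p_half)^2)) * 0.75)
})

test_that("a seeded run is bit-identical on rerun", {
  net <- default_network()
  poly <- default_polygon()
  tab <- flow_table_at(net, poly, 0.02, spacing = 2e-4)
  cfg <- sim_config(N = 40L, gradient_limit = 800, rng_seed = 11L,
                    max_sim_time = 2)
  pol <- waypoint_autopilot(net)
  log1 <- run_simulation(cfg, net, tab, pol, polygon = poly)
  log2 <- run_simulation(cfg, net, tab, pol, polygon = poly)
  expect_identical(log1$outcomes, log2$outcomes)
  expect_identical(log1$records, log2$records)
  expect_identical(log1$final_state$positions, log2$final_state$positions)
})

test_that("zero simulated time yields an empty log and zero success", {
  net <- default_network()
  poly <- default_polygon()
  tab <- flow_table_at(net, poly, 0.02, spacing = 2e-4)
  cfg <- sim_config(N = 10L, max_sim_time = 0)
  log <- run_simulation(cfg, net, tab, constant_policy(c(1, 0)),
                        polygon = poly)
  expect_length(log$records, 0L)
  expect_equal(success_metric(log), 0)
})
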