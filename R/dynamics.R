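# The two-rate integrator. The major loop (MaL) reads the steering input,
# caps it to the gradient limit and logs; the minor loop (MiL) advances the
# physics with the commanded force held constant. The default timing is a
# 0.05 s major period split into 25 minor steps of 0.05/25 = 0.002 s.
# Under the semi-static assumption the inertial term is never evaluated:
# each minor step balances Stokes drag against the applied force, giving the
# particle velocity directly.

#' Simulation configuration
#'
#' @param major_period Major-loop period, s. Default 0.05 (a 20 Hz input
#'   cadence).
#' @param minors_per_major Minor steps per major step. Default 25, giving the
#'   0.002 s integration timestep.
#' @param N Number of particles. Default 500.
#' @param magnetics A [magnetic_params()] object.
#' @param gradient_limit Cap on the commanded gradient magnitude, mT/m.
#'   Default 500 (study range 100-1000).
#' @param viscosity Dynamic viscosity for the drag law, Pa s. Default 1e-3.
#' @param drag_diameter_mode `"particle_d"` (default) uses the individual
#'   particle diameter in the Stokes drag, literally following the drag law;
#'   `"equivalent_Deq"` uses the chain equivalent diameter instead, for
#'   sensitivity studies.
#' @param wall_friction_mu Wall friction coefficient in `[0, 1]`; the
#'   tangential velocity is scaled by `1 - mu` during wall contact. Default 0
#'   (elastic collisions).
#' @param max_sim_time Simulated-time cap per run, s. Default 30; particles
#'   still in transit when it expires count as failures.
#' @param max_reflections Reflection attempts before a particle is declared
#'   stuck in a corner. Default 4.
#' @param rng_seed Integer seed for particle seeding. Default 1.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(major_period = 0.05, minors_per_major = 25L, N = 500L,
                       magnetics = magnetic_params(),
                       gradient_limit = 500, viscosity = 1e-3,
                       drag_diameter_mode = c("particle_d", "equivalent_Deq"),
                       wall_friction_mu = 0, max_sim_time = 30,
                       max_reflections = 4L, rng_seed = 1L) {
  drag_diameter_mode <- match.arg(drag_diameter_mode)
  if (N < 1) stop("sim_config: N must be >= 1")
  if (major_period <= 0 || minors_per_major < 1)
    stop("sim_config: invalid loop timing")
  if (wall_friction_mu < 0 || wall_friction_mu > 1)
    stop("sim_config: wall_friction_mu must lie in [0, 1]")
  structure(list(
    major_period = major_period,
    minors_per_major = as.integer(minors_per_major),
    dt_minor = major_period / minors_per_major,
    N = as.integer(N),
    magnetics = magnetics,
    gradient_limit = gradient_limit,
    viscosity = viscosity,
    drag_diameter_mode = drag_diameter_mode,
    wall_friction_mu = wall_friction_mu,
    max_sim_time = max_sim_time,
    max_reflections = as.integer(max_reflections),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

drag_diameter <- function(config) {
  if (config$drag_diameter_mode == "particle_d") config$magnetics$d
  else config$magnetics$D_eq
}

#' Semi-static particle velocity
#'
#' Balances Stokes drag `-3 pi eta d (v_p - v_f)` against the applied force
#' within one minor step, giving `v_p = v_f + F / (3 pi eta d)`.
#'
#' @param F_applied Length-2 applied force, N.
#' @param v_f Length-2 fluid velocity at the particle, m/s.
#' @param eta Dynamic viscosity, Pa s.
#' @param d_drag Drag diameter, m.
#' @return Length-2 particle velocity, m/s.
#' @export
semi_static_velocity <- function(F_applied, v_f, eta, d_drag) {
  if (eta <= 0 || d_drag <= 0) stop("semi_static_velocity: eta, d_drag > 0")
  v_f + F_applied / (3 * pi * eta * d_drag)
}

#' Particle seeding specification
#'
#' `clump` places all particles uniformly at random in one axis-aligned
#' square near the inlet; `split` divides them equally between that square
#' and a second square located after the first bifurcation. Defaults place
#' the clump square (side 0.8 mm) centred 1 mm downstream of the inlet on
#' the centreline, and the split square centred 6.5 mm downstream (between
#' the first and second junctions).
#'
#' @param mode `"clump"` or `"split"`.
#' @param clump_center,side Centre (length-2, m) and side (m) of the clump
#'   square.
#' @param second_center Centre of the post-bifurcation square (split mode).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(mode = c("clump", "split"),
                      clump_center = c(1e-3, 0), side = 0.8e-3,
                      second_center = c(6.5e-3, 0)) {
  mode <- match.arg(mode)
  if (side <= 0) stop("seed_spec: side must be > 0")
  structure(list(mode = mode, clump_center = clump_center, side = side,
                 second_center = second_center),
            class = "seed_spec")
}

square_corners <- function(center, side) {
  h <- side / 2
  rbind(center + c(-h, -h), center + c(h, -h),
        center + c(h, h), center + c(-h, h))
}

#' Seed the swarm
#'
#' Draws particle positions uniformly i.i.d. in the seeding square(s) from a
#' seeded generator; split mode places `ceiling(N/2)` particles in the clump
#' square and the remainder in the second square. Velocities start at zero
#' and the clock at 0.
#'
#' @param spec A [seed_spec()].
#' @param N Number of particles.
#' @param rng_seed Integer seed.
#' @param polygon `lumen_polygon` used to validate that the squares lie
#'   inside the lumen.
#' @return An object of class `swarm_state`: list with `positions` (N x 2),
#'   `velocities` (N x 2), `status` (`"active"`, `"exited"`, `"stuck"`),
#'   `exit_outlet`, `exit_time`, and clock `t`.
#' @export
seed_particles <- function(spec, N, rng_seed, polygon) {
  stopifnot(inherits(spec, "seed_spec"))
  squares <- list(square_corners(spec$clump_center, spec$side))
  if (spec$mode == "split")
    squares <- c(squares, list(square_corners(spec$second_center, spec$side)))
  for (sq in squares)
    if (!all(point_in_lumen(polygon, sq)))
      stop("invalid seed: seeding square extends outside the lumen")

  counts <- if (spec$mode == "clump") N else c(ceiling(N / 2), floor(N / 2))
  pos <- withr_seed(rng_seed, {
    blocks <- lapply(seq_along(squares), function(i) {
      sq <- squares[[i]]
      cbind(runif(counts[i], min(sq[, 1]), max(sq[, 1])),
            runif(counts[i], min(sq[, 2]), max(sq[, 2])))
    })
    do.call(rbind, blocks)
  })
  structure(list(
    positions = pos,
    velocities = matrix(0, N, 2),
    status = rep("active", N),
    exit_outlet = rep(NA_character_, N),
    exit_time = rep(NA_real_, N),
    t = 0
  ), class = "swarm_state")
}

# evaluate `expr` under a temporary RNG seed, restoring the global state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.swarm_state <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("active", "exited", "stuck")))
  cat("<swarm_state> t =", format(x$t), "s;", tab["active"], "active,",
      tab["exited"], "exited,", tab["stuck"], "stuck\n")
  invisible(x)
}

status_codes <- c(active = 0L, exited = 1L, stuck = 2L)

state_to_int <- function(state) {
  unname(status_codes[state$status])
}

#' Resolve a wall collision by reversal and reflection
#'
#' A proposed move has left the lumen. The wall crossing point is located by
#' bisection (to 1e-9 m) along the trajectory; the residual displacement and
#' the velocity are mirrored about the wall tangent (the particle "bounces"),
#' with the tangential components attenuated by `1 - mu` wall friction. With
#' `mu = 0` the collision is elastic and the speed is preserved exactly. At
#' corners the reflection uses the nearer edge; if the particle cannot be
#' returned to the lumen after `max_reflections` chained reflections it is
#' parked on the boundary and reported unresolved (stuck).
#'
#' @param p_prev Length-2 position inside the lumen.
#' @param p_proposed Length-2 proposed position outside the lumen.
#' @param v_p Length-2 particle velocity, m/s.
#' @param polygon A `lumen_polygon`.
#' @param mu Wall friction coefficient in `[0, 1]`.
#' @param max_reflections Chained reflection attempts before giving up.
#' @return List with `position`, `velocity`, and logical `resolved`.
#' @export
resolve_collision <- function(p_prev, p_proposed, v_p, polygon, mu = 0,
                              max_reflections = 4L) {
  stopifnot(length(p_prev) == 2, length(p_proposed) == 2)
  if (!point_in_lumen(polygon, p_prev))
    stop("resolve_collision: p_prev must lie inside the lumen")
  cpp_resolve_collision(as.numeric(p_prev), as.numeric(p_proposed),
                        as.numeric(v_p), polygon$boundary, mu,
                        as.integer(max_reflections))
}

#' One minor (physics) step
#'
#' Advances every active particle by one minor timestep under a fixed
#' gradient command: sample the fluid velocity at the particle, form the
#' semi-static particle velocity, propose the displaced position, then
#' resolve outlet crossings (the particle exits and is retired) and wall
#' collisions (reversal along the trajectory, reflection, wall friction).
#'
#' @param state A `swarm_state`.
#' @param cmd A `gradient_command`.
#' @param flow A `flow_lookup`.
#' @param polygon A `lumen_polygon`.
#' @param graph The `swarm_network`.
#' @param config A `sim_config`.
#' @param n_steps Number of minor steps to run (default 1).
#' @return The advanced `swarm_state`.
#' @export
minor_step <- function(state, cmd, flow, polygon, graph, config, n_steps = 1L) {
  F <- magnetic_force(config$magnetics, cmd)
  vscale <- 1 / (3 * pi * config$viscosity * drag_diameter(config))
  res <- cpp_run_minors(
    state$positions, state_to_int(state),
    match(state$exit_outlet, names(graph$outlets)),
    ifelse(is.na(state$exit_time), -1, state$exit_time),
    state$t, as.integer(n_steps), config$dt_minor,
    F[1], F[2], vscale,
    config$wall_friction_mu, config$max_reflections,
    polygon$boundary, gate_matrix(graph),
    flow$x0, flow$y0, flow$spacing, flow$nx, flow$ny,
    flow$cell, flow$velocities)
  state$positions <- res$positions
  state$velocities <- res$velocities
  state$status <- names(status_codes)[res$status + 1L]
  state$exit_outlet <- names(graph$outlets)[res$exit_gate]
  state$exit_time <- ifelse(res$exit_time < 0, NA_real_, res$exit_time)
  state$t <- res$t
  state
}

#' One major (input/logging) step
#'
#' Queries the steering policy once, caps the raw input to the gradient
#' limit, runs `minors_per_major` minor steps under the fixed command, and
#' returns the advanced state together with one log record (time, raw input,
#' command, positions).
#'
#' @inheritParams minor_step
#' @param policy A `steering_policy`.
#' @param store_positions Keep a copy of the particle positions in the log
#'   record (default TRUE).
#' @return A list `(state, record)`.
#' @export
major_step <- function(state, policy, flow, polygon, graph, config,
                       store_positions = TRUE) {
  stopifnot(inherits(policy, "steering_policy"))
  raw <- policy$fn(state, graph, graph$goal_outlet, state$t)
  if (!is.numeric(raw) || length(raw) != 2 || anyNA(raw))
    stop("steering policy failure at t = ", state$t,
         ": policy returned ", deparse(raw))
  m <- sqrt(sum(raw^2))
  if (m > 1) raw <- raw / m
  cmd <- limit_gradient(raw, config$gradient_limit)
  t_before <- state$t
  state <- minor_step(state, cmd, flow, polygon, graph, config,
                      n_steps = config$minors_per_major)
  record <- list(t = t_before, raw = raw, gradient = cmd$gradient,
                 positions = if (store_positions) state$positions else NULL)
  list(state = state, record = record)
}

#' Run a full steering simulation
#'
#' Repeats major steps until every particle has exited or got stuck, or the
#' simulated-time cap is reached. With a fixed seed and a deterministic
#' policy the run (and its log) is bit-reproducible.
#'
#' @param config A `sim_config`.
#' @param graph A `swarm_network`.
#' @param flow A `flow_lookup`.
#' @param policy A `steering_policy`.
#' @param seed A [seed_spec()], or a pre-seeded `swarm_state`.
#' @param polygon Optional `lumen_polygon` (rebuilt from `graph` if missing).
#' @param store_positions Keep per-major-step position snapshots in the log.
#' @return An object of class `run_log`; see [success_metric()],
#'   [write_run_log()].
#' @export
run_simulation <- function(config, graph, flow, policy, seed = seed_spec(),
                           polygon = NULL, store_positions = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(polygon)) polygon <- network_to_polygon(graph)
  state <- if (inherits(state <- seed, "swarm_state")) state
           else seed_particles(seed, config$N, config$rng_seed, polygon)
  records <- list()
  k <- 0L
  while (any(state$status == "active") &&
         state$t < config$max_sim_time - 1e-12) {
    step <- major_step(state, policy, flow, polygon, graph, config,
                       store_positions = store_positions)
    state <- step$state
    k <- k + 1L
    records[[k]] <- step$record
  }
  outcomes <- data.frame(
    particle = seq_len(nrow(state$positions)),
    status = state$status,
    exit_outlet = state$exit_outlet,
    exit_time = state$exit_time,
    stringsAsFactors = FALSE
  )
  structure(list(
    records = records,
    outcomes = outcomes,
    final_state = state,
    metadata = list(schema = "microsteer-runlog/1",
                    N = config$N,
                    goal_outlet = graph$goal_outlet,
                    gradient_limit = config$gradient_limit,
                    rng_seed = config$rng_seed,
                    major_period = config$major_period,
                    policy = policy$desc)
  ), class = "run_log")
}

#' @export
print.run_log <- function(x, ...) {
  cat("<run_log> ", length(x$records), " major steps, N = ", x$metadata$N,
      ", goal ", x$metadata$goal_outlet, ", success ",
      round(success_metric(x), 1), "%\n", sep = "")
  invisible(x)
}
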