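# Study harness: the percent-to-goal success metric, 10-repeat parametric
# sweeps over flow velocity / gradient limit / seeding mode, and the
# digital-shadow validation computations (time to travel a fixed distance
# under a uniform gradient, percentage-difference comparison against
# measured times, and frame binarization with centre-of-mass extraction).

#' Percentage of particles that reached the goal outlet
#'
#' `100 x (number of particles with exit outlet equal to the goal) / N`.
#' Particles that exited elsewhere, got stuck, or were still in transit when
#' the run ended all count as failures.
#'
#' @param log A `run_log`.
#' @param goal Goal outlet id; defaults to the goal recorded in the log.
#' @return Percentage in `[0, 100]`.
#' @export
success_metric <- function(log, goal = NULL) {
  stopifnot(inherits(log, "run_log"))
  if (is.null(goal)) goal <- log$metadata$goal_outlet
  oc <- log$outcomes
  100 * sum(!is.na(oc$exit_outlet) & oc$exit_outlet == goal) / nrow(oc)
}

#' Per-outlet exit breakdown
#'
#' Percentages of particles per outlet plus the stuck and in-transit shares;
#' the rows sum to 100.
#'
#' @param log A `run_log`.
#' @return Named numeric vector of percentages.
#' @export
outcome_breakdown <- function(log) {
  oc <- log$outcomes
  N <- nrow(oc)
  outlets <- sort(unique(oc$exit_outlet[!is.na(oc$exit_outlet)]))
  out <- vapply(outlets, function(o)
    100 * sum(!is.na(oc$exit_outlet) & oc$exit_outlet == o) / N, numeric(1))
  c(out,
    stuck = 100 * sum(oc$status == "stuck") / N,
    in_transit = 100 * sum(oc$status == "active") / N)
}

#' Run a parametric steering sweep
#'
#' For each parameter value, performs `repeats` independently seeded runs of
#' the full steering simulation and reports the mean and sample standard
#' deviation of the success percentage. Sweepable parameters are the inlet
#' flow velocity (`flow_velocity`, m/s; the flow field is re-solved per
#' value), the gradient limit (`gradient_limit`, mT/m) and the seeding mode
#' (`seed_mode`, `"clump"`/`"split"`). Deterministic given the seed list.
#'
#' @param parameter One of `"flow_velocity"`, `"gradient_limit"`,
#'   `"seed_mode"`.
#' @param values Vector of parameter values.
#' @param graph A `swarm_network`.
#' @param base_config A `sim_config` providing all non-swept settings.
#' @param policy_factory Function `(graph)` returning a `steering_policy`.
#'   Default builds the [waypoint_autopilot()].
#' @param repeats Runs per value. Default 10.
#' @param seeds Integer seeds, length `repeats`. Default `1:repeats`.
#' @param base_flow_velocity Inlet central velocity used when `parameter` is
#'   not `flow_velocity`. Default 0.005 m/s.
#' @param seed Base [seed_spec()] (ignored when sweeping `seed_mode`).
#' @return An object of class `sweep_result`: a data frame with columns
#'   `parameter`, `value`, `mean_pct`, `sd_pct`, `repeats`, with the
#'   per-run success matrix in attribute `"runs"`.
#' @export
run_sweep <- function(parameter = c("flow_velocity", "gradient_limit",
                                    "seed_mode"),
                      values, graph, base_config = sim_config(),
                      policy_factory = waypoint_autopilot,
                      repeats = 10L, seeds = seq_len(repeats),
                      base_flow_velocity = 0.005, seed = seed_spec()) {
  parameter <- match.arg(parameter)
  if (length(seeds) != repeats)
    stop("run_sweep: need exactly `repeats` seeds")
  if (repeats == 1L)
    warning("run_sweep: a single repeat gives no spread; SD reported as 0")
  polygon <- network_to_polygon(graph)
  policy <- policy_factory(graph)
  flow_for <- function(v)
    build_lookup_table(graph, solve_network_flow(graph, flow_config(v)),
                       polygon)
  base_flow <- if (parameter != "flow_velocity") flow_for(base_flow_velocity)

  runs <- matrix(NA_real_, length(values), repeats)
  for (i in seq_along(values)) {
    v <- values[[i]]
    cfg <- base_config
    sd_spec <- seed
    flow <- base_flow
    if (parameter == "flow_velocity") {
      if (v < 0.005 - 1e-12 || v > 0.06 + 1e-12)
        warning("flow velocity ", v, " m/s outside the study range 0.005-0.06")
      flow <- flow_for(v)
    } else if (parameter == "gradient_limit") {
      if (v < 100 - 1e-9 || v > 1000 + 1e-9)
        warning("gradient limit ", v, " mT/m outside the study range 100-1000")
      cfg$gradient_limit <- v
    } else {
      sd_spec <- seed_spec(mode = as.character(v))
    }
    for (r in seq_len(repeats)) {
      cfg$rng_seed <- as.integer(seeds[r])
      log <- run_simulation(cfg, graph, flow, policy, sd_spec,
                            polygon = polygon, store_positions = FALSE)
      runs[i, r] <- success_metric(log)
    }
  }
  res <- data.frame(
    parameter = parameter,
    value = if (parameter == "seed_mode") as.character(values) else values,
    mean_pct = rowMeans(runs),
    sd_pct = if (repeats > 1L) apply(runs, 1, sd) else 0,
    repeats = as.integer(repeats),
    stringsAsFactors = FALSE
  )
  attr(res, "runs") <- runs
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Time for the swarm to travel a fixed distance under a uniform gradient
#'
#' Digital shadow of the open-workspace validation experiment: particles on
#' a flat substrate, no vessel and no flow, a spatially uniform gradient.
#' Under the semi-static model the swarm translates at the constant velocity
#' `v_p = F / (3 pi eta d)`, so the travel time has the closed form
#' `distance / |v_p|`. With `simulate = TRUE` the same quantity is measured
#' by stepping the minor-loop kinematics explicitly, as a cross-check.
#'
#' @param params A `magnetic_params`.
#' @param gradient Gradient magnitude, mT/m.
#' @param distance Distance to travel, m. Default 1e-3 (1 mm).
#' @param eta Viscosity, Pa s. Default 1e-3.
#' @param d_drag Drag diameter, m. Default the individual particle diameter.
#' @param simulate Measure by explicit minor-step integration instead of the
#'   closed form.
#' @param dt Minor timestep for the simulated variant, s.
#' @return Time in seconds. A zero gradient (no force) yields `Inf` with
#'   attribute `stationary = TRUE`, mirroring the below-threshold
#'   experimental case where the particles never move.
#' @export
time_to_travel <- function(params, gradient, distance = 1e-3, eta = 1e-3,
                           d_drag = params$d, simulate = FALSE, dt = 0.002) {
  stopifnot(inherits(params, "magnetic_params"))
  if (distance <= 0) stop("time_to_travel: distance must be > 0")
  F <- magnetic_force(params, c(gradient, 0))
  speed <- sqrt(sum(semi_static_velocity(F, c(0, 0), eta, d_drag)^2))
  if (speed == 0)
    return(structure(Inf, stationary = TRUE))
  if (!simulate) return(distance / speed)
  x <- 0; t <- 0
  v <- semi_static_velocity(F, c(0, 0), eta, d_drag)[1]
  while (x < distance) {
    x <- x + v * dt
    t <- t + dt
  }
  # linear interpolation within the crossing step
  t - (x - distance) / v
}

#' Mean absolute percentage difference between paired observations
#'
#' `mean(100 |sim - exp| / exp)` over paired values, the deviation measure
#' used to compare simulated and measured travel times.
#'
#' @param sim,exp Equal-length numeric vectors; `exp` strictly positive.
#' @return Percentage.
#' @export
percentage_difference <- function(sim, exp) {
  if (length(sim) != length(exp))
    stop("percentage_difference: input lengths differ")
  if (any(exp <= 0)) stop("percentage_difference: exp values must be > 0")
  mean(100 * abs(sim - exp) / exp)
}

#' Binarize a grayscale frame and return the particle centre of mass
#'
#' Dark particles on a light background: pixels strictly below the threshold
#' form the foreground mask, whose centre of mass is returned in pixel
#' coordinates `(x = column, y = row)`, or in millimetres when a pixel scale
#' is supplied. The default threshold is Otsu's, computed on the frame.
#'
#' @param image Numeric matrix (rows y, columns x), any intensity range.
#' @param threshold Intensity threshold; default `EBImage::otsu()` on the
#'   frame's own range.
#' @param px_per_mm Optional scale; if given, the centroid is returned in mm.
#' @return Length-2 centroid `(x, y)`.
#' @export
binarize_and_centroid <- function(image, threshold = NULL, px_per_mm = NULL) {
  image <- as.matrix(image)
  if (length(image) == 0) stop("binarize_and_centroid: empty image")
  if (is.null(threshold)) {
    rg <- range(image)
    if (rg[1] == rg[2])
      stop("no particles found: image is uniform")
    threshold <- EBImage::otsu(image, range = rg)
  }
  mask <- image < threshold
  if (!any(mask)) stop("no particles found below the threshold")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, "col"]) - 1, y = mean(idx[, "row"]) - 1)
  if (!is.null(px_per_mm)) centroid <- centroid / px_per_mm
  centroid
}

#' Write a sweep summary CSV
#'
#' Columns `parameter, value, mean_pct, sd_pct, repeats`, one row per swept
#' value.
#'
#' @param result A `sweep_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  write.csv(as.data.frame(result)[, c("parameter", "value", "mean_pct",
                                      "sd_pct", "repeats")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a run log as JSON lines
#'
#' The first line holds the metadata (including a schema version), the
#' second the per-particle outcomes, and each following line one major-step
#' record (t, raw input, commanded gradient, optional positions). A log
#' written by a different schema version is rejected explicitly rather than
#' silently misparsed. The round trip preserves all fields.
#'
#' @param log A `run_log`.
#' @param path File path (conventionally `.jsonl`).
#' @return `write_run_log` returns `path` invisibly; `read_run_log` a
#'   `run_log`.
#' @export
write_run_log <- function(log, path) {
  stopifnot(inherits(log, "run_log"))
  con <- file(path, "w")
  on.exit(close(con))
  wline <- function(x)
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns", null = "null"), con)
  wline(log$metadata)
  wline(log$outcomes)
  for (rec in log$records) wline(rec)
  invisible(path)
}

#' @rdname write_run_log
#' @export
read_run_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("run log file is truncated: ", path)
  metadata <- jsonlite::fromJSON(lines[1])
  if (!identical(metadata$schema, "microsteer-runlog/1"))
    stop("unsupported run log schema version: ", metadata$schema)
  outcomes <- as.data.frame(jsonlite::fromJSON(lines[2]))
  # all-NA columns deserialize as logical; restore the schema types
  outcomes$particle <- as.integer(outcomes$particle)
  outcomes$status <- as.character(outcomes$status)
  outcomes$exit_outlet <- as.character(outcomes$exit_outlet)
  outcomes$exit_time <- as.numeric(outcomes$exit_time)
  records <- lapply(lines[-(1:2)], function(l) {
    rec <- jsonlite::fromJSON(l)
    if (!is.null(rec$positions)) rec$positions <- as.matrix(rec$positions)
    rec
  })
  structure(list(records = records, outcomes = outcomes,
                 final_state = NULL, metadata = metadata),
            class = "run_log")
}
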