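# Steering policies: scripted stand-ins for the human operator and the
# haptic input device. A policy maps (swarm state, network, goal, time) to a
# raw dimensionless 2D input of magnitude at most 1; the major loop scales
# it by the gradient limit to form the commanded gradient.

new_policy <- function(fn, desc) {
  structure(list(fn = fn, desc = desc), class = "steering_policy")
}

#' @export
print.steering_policy <- function(x, ...) {
  cat("<steering_policy>", x$desc, "\n")
  invisible(x)
}

clamp_unit <- function(v) {
  m <- sqrt(sum(v^2))
  if (is.finite(m) && m > 1) v / m else v
}

#' Constant-input steering policy
#'
#' Returns the same raw input at every query (useful for open-loop studies
#' and for the digital-shadow validation, where a constant gradient is
#' applied across the workspace).
#'
#' @param raw Length-2 dimensionless input; renormalized to magnitude 1 if
#'   larger.
#' @return A `steering_policy`.
#' @export
constant_policy <- function(raw = c(0, 0)) {
  raw <- clamp_unit(as.numeric(raw))
  new_policy(function(state, graph, goal, t) raw,
             sprintf("constant(%.3f, %.3f)", raw[1], raw[2]))
}

#' Replay a recorded input log
#'
#' Returns, at each major step, the raw input recorded at the matching major
#' step of an earlier run; zero input after the log ends (with a one-time
#' warning for a missing record). Replaying a run's own log with the same
#' seed reproduces the run bit-identically.
#'
#' @param log A `run_log`.
#' @return A `steering_policy`.
#' @export
replay_policy <- function(log) {
  stopifnot(inherits(log, "run_log"))
  inputs <- lapply(log$records, `[[`, "raw")
  period <- log$metadata$major_period
  warned <- FALSE
  new_policy(function(state, graph, goal, t) {
    idx <- as.integer(round(t / period)) + 1L
    if (idx >= 1L && idx <= length(inputs)) return(inputs[[idx]])
    if (!warned && length(inputs) > 0L) {
      warning("replay_policy: no recorded input at major step ", idx,
              "; emitting zero input")
      warned <<- TRUE
    }
    c(0, 0)
  }, sprintf("replay(%d records)", length(inputs)))
}

#' Waypoint plan along the inlet-to-goal path
#'
#' Builds the guidance plan used by [waypoint_autopilot()]: corridor points
#' above each junction on the main channel, offset toward the goal-side
#' (upper) wall so the swarm is kept out of the suction wedge of the
#' downward branches, followed by a final target beyond the goal gate.
#'
#' @param graph A `swarm_network`.
#' @param goal Goal outlet id.
#' @param corridor_offset Transverse offset of the corridor from the main
#'   centreline, m. Default `0.3 * width` (toward the upper wall).
#' @return An object of class `waypoint_plan`: list with `waypoints`
#'   (k x 2 matrix), `goal_gate_center`, `beyond` (point past the gate),
#'   `corridor_y`, and for branch goals the junction x `x_descend`.
#' @export
waypoint_plan <- function(graph, goal = graph$goal_outlet,
                          corridor_offset = 0.3 * graph$width) {
  if (!goal %in% names(graph$outlets))
    stop("waypoint planning error: unreachable goal '", goal, "'")
  w <- graph$width
  gate <- graph$outlets[[goal]]
  gate_center <- colMeans(gate)
  y_cor <- corridor_offset
  xj <- vapply(graph$junctions, function(j) j$node[1], numeric(1))
  if (goal == "main_end") {
    keep <- sort(xj)
    x_descend <- gate_center[1] - w       # begin final approach here
    beyond <- gate_center + c(2 * w, 0)
  } else {
    j_goal <- as.integer(sub("branch_", "", goal))
    keep <- sort(xj[xj < xj[j_goal]])
    x_descend <- xj[j_goal] - w
    # straight out of the branch: past the gate along the branch axis
    axis <- gate_center - c(xj[j_goal], 0)
    axis <- axis / sqrt(sum(axis^2))
    beyond <- gate_center + 2 * w * axis
  }
  wps <- cbind(c(keep, x_descend), rep(y_cor, length(keep) + 1L))
  structure(list(waypoints = wps, goal_gate_center = gate_center,
                 beyond = beyond, corridor_y = y_cor, x_descend = x_descend),
            class = "waypoint_plan")
}

#' Waypoint autopilot policy
#'
#' A deterministic scripted stand-in for an experienced human operator. The
#' controller has three phases, recomputed purely from the current state:
#'
#' 1. *Climb*: while any active particle is still below a clearance band
#'    above the main centreline (and the swarm has not yet reached the
#'    descent zone), push straight toward the upper wall. This parks the
#'    swarm in a corridor along the goal-side wall, out of reach of the
#'    downward-branch suction wedges at the junctions.
#' 2. *Cruise*: steer the active-swarm centroid toward the next waypoint of
#'    the [waypoint_plan()] at least `capture_radius` ahead of it, keeping
#'    the swarm in the corridor while the flow carries it downstream.
#' 3. *Final approach*: past the last waypoint, steer toward the point
#'    beyond the goal gate until every particle has exited.
#'
#' The output is the unit vector toward the current target scaled by `gain`
#' and clamped to magnitude 1.
#'
#' @param graph A `swarm_network`.
#' @param goal Goal outlet id. Default the network goal.
#' @param capture_radius Look-ahead distance for waypoint hand-off, m.
#'   Default `width / 2`.
#' @param gain Scalar gain on the unit direction. Default 1 (full authority).
#' @param corridor_offset Corridor offset passed to [waypoint_plan()].
#' @param clearance Climb phase ends once every active particle is above
#'   this height over the main centreline, m. Default `0.1 * width`.
#' @return A `steering_policy`.
#' @export
waypoint_autopilot <- function(graph, goal = graph$goal_outlet,
                               capture_radius = graph$width / 2, gain = 1,
                               corridor_offset = 0.3 * graph$width,
                               clearance = 0.1 * graph$width) {
  plan <- waypoint_plan(graph, goal, corridor_offset)
  fn <- function(state, graph, goal, t) {
    active <- state$status == "active"
    if (!any(active)) return(c(0, 0))
    pos <- state$positions[active, , drop = FALSE]
    centroid <- colMeans(pos)
    in_descent <- centroid[1] >= plan$x_descend
    if (!in_descent && min(pos[, 2]) < clearance) {
      dir <- c(0, 1)                       # climb to the goal-side wall
    } else {
      if (in_descent) {
        target <- plan$beyond
      } else {
        ahead <- plan$waypoints[, 1] >= centroid[1] + capture_radius
        target <- if (any(ahead))
          plan$waypoints[which(ahead)[1], ] else plan$beyond
      }
      d <- target - centroid
      dir <- d / sqrt(sum(d^2))
    }
    clamp_unit(gain * dir)
  }
  new_policy(fn, sprintf("waypoint_autopilot(goal=%s, gain=%.2f)", goal, gain))
}

#' Map a haptic-handle displacement to a raw steering input
#'
#' Pure-function model of the input mapping of a desktop haptic device with
#' an approximately 10 cm x 10 cm planar workspace: the raw input is the
#' handle displacement divided by the workspace half-width, clamped to unit
#' magnitude. The restoring spring that recentres the physical handle is a
#' device-side property; its force (stiffness sized so that full deflection
#' gives the 4 N maximum) is returned as an advisory value for interface
#' completeness.
#'
#' @param displacement Length-2 handle displacement from rest, m.
#' @param workspace_halfwidth Workspace half-width, m. Default 0.05.
#' @return List with `raw` (length-2, magnitude <= 1) and `spring_force`
#'   (length-2, N, magnitude capped at 4 N).
#' @export
haptic_workspace_mapping <- function(displacement, workspace_halfwidth = 0.05) {
  if (workspace_halfwidth <= 0) stop("workspace_halfwidth must be > 0")
  raw <- clamp_unit(displacement / workspace_halfwidth)
  k <- 4 / 0.05                           # N/m: 4 N at full 5 cm deflection
  spring <- -k * displacement
  m <- sqrt(sum(spring^2))
  if (m > 4) spring <- spring * (4 / m)
  list(raw = raw, spring_force = spring)
}
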