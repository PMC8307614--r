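#' Configuration for the synthetic monolayer simulator
#'
#' Parameters of a Vicsek-style agent model of a confluent cell monolayer.
#' `coupling` is the neighbor-alignment strength and stands in for the
#' biological knob that tunes collectivity (calcium-dependent E-cadherin
#' adhesion): it is abstract and dimensionless, not a concentration.
#' `field_bias` pulls headings toward +x and stands in for a horizontal
#' directional command such as a DC electric field. The model encodes the
#' speed/coordination trade-off seen in strongly adhesive tissues through
#' `speed_coupling_slope`.
#'
#' @param n_agents number of agents.
#' @param box_width,box_height domain size, um.
#' @param coupling neighbor-alignment strength, dimensionless >= 0.
#' @param noise angular noise half-width, radians in `[0, pi]`; each step a
#'   uniform perturbation in `[-noise, +noise]` is added to every heading.
#' @param field_bias weight pulling headings toward angle 0 (+x),
#'   dimensionless >= 0. May be a scalar or a vector of length
#'   `n_frames - 1` giving a per-step schedule (e.g. stimulation switched on
#'   mid-run).
#' @param base_speed agent speed at zero coupling, um/min > 0.
#' @param speed_coupling_slope linear decrease of speed with coupling,
#'   dimensionless >= 0; speed is floored at 10% of `base_speed`.
#' @param interaction_radius neighborhood radius for alignment, um > 0.
#' @param dt time step (frame interval), min > 0.
#' @param n_frames number of recorded frames (>= 1).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @param boundary_mode `"periodic"` (torus) or `"free_x_edges"` (periodic
#'   in y only, so the tissue has free left/right edges).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_agents = 400, box_width = 400, box_height = 400,
                       coupling = 1, noise = 0.8, field_bias = 0,
                       base_speed = 1.5, speed_coupling_slope = 0.15,
                       interaction_radius = 40, dt = 5, n_frames = 108,
                       seed = 1L,
                       boundary_mode = c("periodic", "free_x_edges")) {
  boundary_mode <- match.arg(boundary_mode)
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  if (!is.numeric(n_agents) || length(n_agents) != 1 || n_agents < 1 || n_agents != round(n_agents))
    stop("'n_agents' must be a positive integer", call. = FALSE)
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 1 || n_frames != round(n_frames))
    stop("'n_frames' must be a positive integer", call. = FALSE)
  chk_pos(box_width, "box_width"); chk_pos(box_height, "box_height")
  chk_pos(base_speed, "base_speed"); chk_pos(interaction_radius, "interaction_radius")
  chk_pos(dt, "dt")
  if (!is.numeric(coupling) || length(coupling) != 1 || coupling < 0)
    stop("'coupling' must be >= 0", call. = FALSE)
  if (!is.numeric(noise) || length(noise) != 1 || noise < 0 || noise > pi)
    stop("'noise' must lie in [0, pi]", call. = FALSE)
  if (!is.numeric(field_bias) || any(field_bias < 0) ||
      !(length(field_bias) == 1 || length(field_bias) == n_frames - 1))
    stop("'field_bias' must be >= 0, scalar or length n_frames - 1", call. = FALSE)
  if (!is.numeric(speed_coupling_slope) || length(speed_coupling_slope) != 1 || speed_coupling_slope < 0)
    stop("'speed_coupling_slope' must be >= 0", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("'seed' must be an integer", call. = FALSE)
  structure(list(
    n_agents = as.integer(n_agents), box_width = box_width,
    box_height = box_height, coupling = coupling, noise = noise,
    field_bias = field_bias, base_speed = base_speed,
    speed_coupling_slope = speed_coupling_slope,
    interaction_radius = interaction_radius, dt = dt,
    n_frames = as.integer(n_frames), seed = as.integer(seed),
    boundary_mode = boundary_mode
  ), class = "sim_config")
}

# Evaluate code with a private RNG stream; the caller's RNG state is restored.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a monolayer of aligning agents
#'
#' Runs a Vicsek-style model: each step, agent i forms a target direction
#' from three unit-vector pulls -- its own heading (weight 1, persistence),
#' the circular mean heading of all agents within `interaction_radius`
#' (self included; weight `coupling`), and the +x axis (weight
#' `field_bias`) -- takes the direction of their weighted sum, adds uniform
#' angular noise in `[-noise, +noise]`, and advances by `speed * dt` along
#' the new heading. Speed is
#' `max(base_speed * (1 - speed_coupling_slope * coupling), 0.1 * base_speed)`,
#' so more strongly coupled tissues move more slowly, mirroring the
#' adhesion/speed trade-off of real monolayers. The relative weight of the
#' directional command is thus `field_bias / (1 + coupling + field_bias)`:
#' strong native coordination dilutes the command.
#'
#' With `coupling = 0` the persistence term keeps each agent on its previous
#' heading (ties and empty neighborhoods likewise default to the agent's own
#' heading).
#'
#' @param config a [sim_config()].
#' @return an `agent_trajectory`: list with matrices `x`, `y` (um),
#'   `heading` (radians in `(-pi, pi]`), `speed` (um/min), each
#'   `n_frames x n_agents`, plus the `config`.
#' @export
simulate_monolayer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_agents; Tn <- config$n_frames
  W <- config$box_width; H <- config$box_height
  speed <- max(config$base_speed * (1 - config$speed_coupling_slope * config$coupling),
               0.1 * config$base_speed)
  bias <- config$field_bias
  if (length(bias) == 1) bias <- rep(bias, max(Tn - 1, 0))
  step <- speed * config$dt
  periodic_x <- config$boundary_mode == "periodic"
  r2 <- config$interaction_radius^2

  with_seed(config$seed, {
    x <- matrix(NA_real_, Tn, n); y <- matrix(NA_real_, Tn, n)
    h <- matrix(NA_real_, Tn, n)
    x[1, ] <- runif(n, 0, W); y[1, ] <- runif(n, 0, H)
    h[1, ] <- runif(n, -pi, pi)
    if (Tn > 1) for (t in seq_len(Tn - 1)) {
      ht <- h[t, ]
      ux <- cos(ht); uy <- sin(ht)
      if (config$coupling > 0) {
        dx <- abs(outer(x[t, ], x[t, ], "-"))
        if (periodic_x) dx <- pmin(dx, W - dx)
        dy <- abs(outer(y[t, ], y[t, ], "-"))
        dy <- pmin(dy, H - dy)
        A <- (dx * dx + dy * dy) <= r2
        mx <- A %*% ux; my <- A %*% uy
        mn <- sqrt(mx^2 + my^2)
        # exact cancellation: fall back to the agent's own heading
        z <- mn < 1e-12
        mx <- ifelse(z, ux, mx / pmax(mn, 1e-12))
        my <- ifelse(z, uy, my / pmax(mn, 1e-12))
      } else {
        mx <- ux; my <- uy  # unused (weight 0), placeholder
      }
      dxv <- ux + config$coupling * mx + bias[t]
      dyv <- uy + config$coupling * my
      deg <- sqrt(dxv^2 + dyv^2) < 1e-12
      dxv <- ifelse(deg, ux, dxv); dyv <- ifelse(deg, uy, dyv)
      hn <- atan2(dyv, dxv) + runif(n, -config$noise, config$noise)
      hn <- hn - 2 * pi * floor((hn + pi) / (2 * pi))  # wrap to [-pi, pi)
      hn[hn <= -pi] <- pi
      h[t + 1, ] <- hn
      xn <- x[t, ] + step * cos(hn)
      yn <- y[t, ] + step * sin(hn)
      if (periodic_x) xn <- xn %% W
      yn <- yn %% H
      x[t + 1, ] <- xn; y[t + 1, ] <- yn
    }
    structure(list(x = x, y = y, heading = h,
                   speed = matrix(speed, Tn, n), config = config),
              class = "agent_trajectory")
  })
}

#' @export
print.agent_trajectory <- function(x, ...) {
  cat(sprintf("<agent_trajectory> %d agents, %d frames, coupling=%.3g, noise=%.3g\n",
              x$config$n_agents, x$config$n_frames, x$config$coupling,
              x$config$noise))
  invisible(x)
}

#' Bin agent displacements onto a velocity grid
#'
#' Adapter so that simulated trajectories feed the same metric and kymograph
#' code as PIV output. The velocity of each agent at `frame` is its
#' displacement to the next frame divided by `dt` (minimum-image wrapped for
#' periodic boundaries); velocities are averaged per cell of a regular grid
#' of spacing `grid_spacing`, and empty cells are marked invalid.
#'
#' @param traj an `agent_trajectory` from [simulate_monolayer()].
#' @param frame frame index (1-based), `frame < n_frames`.
#' @param grid_spacing grid cell size, um.
#' @return a [velocity_field()] with `pixel_size = 1` um/px and
#'   `frame_interval = dt`.
#' @export
trajectory_to_field <- function(traj, frame, grid_spacing = 40) {
  stopifnot(inherits(traj, "agent_trajectory"))
  cfg <- traj$config
  if (frame < 1 || frame >= cfg$n_frames)
    stop("'frame' must satisfy 1 <= frame < n_frames", call. = FALSE)
  dx <- traj$x[frame + 1, ] - traj$x[frame, ]
  dy <- traj$y[frame + 1, ] - traj$y[frame, ]
  if (cfg$boundary_mode == "periodic")
    dx <- dx - cfg$box_width * round(dx / cfg$box_width)
  dy <- dy - cfg$box_height * round(dy / cfg$box_height)
  u <- dx / cfg$dt; v <- dy / cfg$dt
  nx <- max(1, ceiling(cfg$box_width / grid_spacing))
  ny <- max(1, ceiling(cfg$box_height / grid_spacing))
  ix <- pmin(pmax(floor(traj$x[frame, ] / grid_spacing) + 1, 1), nx)
  iy <- pmin(pmax(floor(traj$y[frame, ] / grid_spacing) + 1, 1), ny)
  cell <- (ix - 1) * ny + iy
  um <- matrix(NA_real_, ny, nx); vm <- matrix(NA_real_, ny, nx)
  cnt <- matrix(0, ny, nx)
  su <- rowsum(u, cell); sv <- rowsum(v, cell)
  nn <- rowsum(rep(1, length(cell)), cell)
  id <- as.integer(rownames(su))
  um[id] <- su / nn; vm[id] <- sv / nn; cnt[id] <- nn
  velocity_field(um, vm,
                 x = (seq_len(nx) - 0.5) * grid_spacing,
                 y = (seq_len(ny) - 0.5) * grid_spacing,
                 valid = cnt > 0,
                 pixel_size = 1, frame_interval = cfg$dt, units = "um_min")
}

#' Velocity fields for every frame pair of a trajectory
#'
#' @inheritParams trajectory_to_field
#' @return list of `n_frames - 1` [velocity_field()] objects.
#' @export
trajectory_fields <- function(traj, grid_spacing = 40) {
  stopifnot(inherits(traj, "agent_trajectory"))
  lapply(seq_len(traj$config$n_frames - 1), trajectory_to_field,
         traj = traj, grid_spacing = grid_spacing)
}
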