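#' Initialise a chain of agents in the premigratory band
#'
#' Agents are stacked single file along the dorsoventral axis, front (first
#' pattern entry) most ventral at the edge of the premigratory band, with
#' surfaces separated by a small packing gap and headings pointing ventrally
#' (+y) with a small seeded angular jitter. Chains whose stacked length
#' exceeds the dorsal space available (`y_premigratory - y_min`) raise a
#' configuration error.
#'
#' @param comp a [composition()].
#' @param arena_ a [arena()].
#' @param params a [model_params()].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   before drawing the jitter (otherwise the current RNG stream is used).
#' @return data.frame of agent states: `agent_id`, `identity`, `x`, `y`,
#'   `hx`, `hy` (unit heading), `radius`, `speed`, `persist`.
#' @export
#' @examples
#' init_chain(composition("LFFF"), arena(), model_params(), seed = 1)
init_chain <- function(comp, arena_ = arena(), params = model_params(),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- as.character(comp)
  n <- length(ids)
  r <- identity_vec(params$cell_radius, ids)
  v <- identity_vec(params$base_speed, ids)
  gap <- params$pack_gap
  stacked <- sum(2 * r) + (n - 1) * gap
  capacity <- arena_$y_premigratory - arena_$y_min
  if (stacked > capacity)
    stop(sprintf(paste0("chain of %d agents needs %.1f um of dorsoventral ",
                        "space but only %.1f um is available dorsal of the ",
                        "premigratory band edge"), n, stacked, capacity))
  y <- numeric(n)
  y[1] <- arena_$y_premigratory - r[1]
  if (n > 1)
    for (i in 2:n) y[i] <- y[i - 1] - r[i - 1] - r[i] - gap
  x <- rep(arena_$width / 2, n)
  jit <- rnorm(n, 0, 0.05)
  data.frame(agent_id = seq_len(n), identity = ids, x = x, y = y,
             hx = -sin(jit), hy = cos(jit), radius = r, speed = v,
             persist = 0L, stringsAsFactors = FALSE)
}

#' Contact-inhibition repolarisation for one pair of agents
#'
#' Given two agents in contact, returns their post-collision headings. Under
#' differential CIL, contacts between agents of the same identity leave both
#' headings unchanged. Otherwise each heading is rotated away from the
#' partner (towards the centre-to-centre escape direction) by at most that
#' agent's CIL turn angle, so the turn magnitude is monotone in the agent's
#' own CIL intensity level. Coincident centres use a random escape axis
#' drawn from the current RNG stream.
#'
#' @param a,b single-row agent data.frames (as produced by [init_chain()]).
#' @param params a [model_params()].
#' @return list with unit 2-vectors `heading_a` and `heading_b`.
#' @export
resolve_cil <- function(a, b, params = model_params()) {
  ha <- c(a$hx, a$hy); hb <- c(b$hx, b$hy)
  if (params$cil_mode == "off" ||
      (params$cil_mode == "differential" && a$identity == b$identity))
    return(list(heading_a = ha, heading_b = hb))
  theta <- resolve_level(params, "theta")
  d <- c(a$x - b$x, a$y - b$y)
  len <- sqrt(sum(d^2))
  if (len < 1e-9) {
    ang <- runif(1, 0, 2 * pi)
    u <- c(cos(ang), sin(ang))
  } else {
    u <- d / len
  }
  list(heading_a = rotate_towards_r(ha, u, theta[[a$identity]]),
       heading_b = rotate_towards_r(hb, -u, theta[[b$identity]]))
}

# R mirror of the C++ bounded rotation towards a target direction.
rotate_towards_r <- function(h, u, theta) {
  ang <- atan2(h[1] * u[2] - h[2] * u[1], h[1] * u[1] + h[2] * u[2])
  if (abs(ang) < 1e-12 || theta <= 0) return(h)
  a <- sign(ang) * min(theta, abs(ang))
  out <- c(cos(a) * h[1] - sin(a) * h[2], sin(a) * h[1] + cos(a) * h[2])
  out / sqrt(sum(out^2))
}

#' Co-attraction displacement for one agent
#'
#' Displacement (um, for one step) of the focal agent towards the centroid
#' of its neighbourhood at a distance: the nearest agent beyond surface
#' contact but within `coattraction_range` on each side (ventral and
#' dorsal) of the focal cell. Magnitude is the co-attraction strength
#' times `dt`; zero when no neighbour is in that band. Co-attraction
#' pulls together cells at a distance -- touching cells exert no pull,
#' and capping the neighbourhood at one cell per side makes a single-file
#' chain behave as a train of tension links rather than collapsing into
#' a cluster.
#'
#' @param focal single-row agent data.frame.
#' @param others data.frame of other agents (may be empty).
#' @param params a [model_params()].
#' @return a 2-vector displacement.
#' @export
coattraction_displacement <- function(focal, others,
                                      params = model_params()) {
  if (nrow(others) == 0) return(c(0, 0))
  dx <- others$x - focal$x
  dy <- others$y - focal$y
  dd <- sqrt(dx^2 + dy^2)
  inr <- dd > focal$radius + others$radius & dd <= params$coattraction_range
  if (!any(inr)) return(c(0, 0))
  ventral <- inr & others$y >= focal$y
  dorsal <- inr & others$y < focal$y
  pick <- c(if (any(ventral)) which(ventral)[which.min(dd[ventral])],
            if (any(dorsal)) which(dorsal)[which.min(dd[dorsal])])
  v <- c(mean(others$x[pick]) - focal$x, mean(others$y[pick]) - focal$y)
  len <- sqrt(sum(v^2))
  if (len < 1e-12) return(c(0, 0))
  eps <- resolve_level(params, "eps")
  eps * params$dt * v / len
}

#' Advance a chain by one time step (reference implementation)
#'
#' Applies, in this fixed order (the order is part of the model contract):
#' intrinsic motility, CIL repolarisation for newly contacting pairs,
#' co-attraction, volume exclusion (a soft spring recovering a fraction of
#' each pair's overlap), heading noise (suppressed for `cil_persist` steps
#' after a repolarisation), and reflective boundaries. This pure-R
#' implementation draws random numbers in exactly the same order as the
#' compiled loop used by [simulate_chain()], so a single step of either
#' agrees to machine precision under the same seed (both treat all
#' contacts as new at the first step).
#'
#' @param agents agent data.frame (see [init_chain()]).
#' @param params a [model_params()].
#' @param arena_ a [arena()].
#' @return the updated agent data.frame.
#' @export
step_chain <- function(agents, params = model_params(), arena_ = arena()) {
  n <- nrow(agents)
  theta_id <- resolve_level(params, "theta")
  eps <- resolve_level(params, "eps")
  # 1. motility
  agents$x <- agents$x + agents$speed * params$dt * agents$hx
  agents$y <- agents$y + agents$speed * params$dt * agents$hy
  # 2. CIL
  if (params$cil_mode != "off" && n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (params$cil_mode == "differential" &&
          agents$identity[i] == agents$identity[j]) next
      d <- c(agents$x[i] - agents$x[j], agents$y[i] - agents$y[j])
      len <- sqrt(sum(d^2))
      if (len >= agents$radius[i] + agents$radius[j] + params$contact_tol)
        next
      if (len < 1e-9) {
        ang <- runif(1, 0, 2 * pi)
        u <- c(cos(ang), sin(ang))
      } else u <- d / len
      ti <- theta_id[[agents$identity[i]]]
      tj <- theta_id[[agents$identity[j]]]
      agents$x[i] <- agents$x[i] + params$cil_push_scale * ti * params$dt * u[1]
      agents$y[i] <- agents$y[i] + params$cil_push_scale * ti * params$dt * u[2]
      agents$x[j] <- agents$x[j] - params$cil_push_scale * tj * params$dt * u[1]
      agents$y[j] <- agents$y[j] - params$cil_push_scale * tj * params$dt * u[2]
      if (ti > 0) {
        h <- rotate_towards_r(c(agents$hx[i], agents$hy[i]), u, ti)
        agents$hx[i] <- h[1]; agents$hy[i] <- h[2]
        agents$persist[i] <- params$cil_persist
      }
      if (tj > 0) {
        h <- rotate_towards_r(c(agents$hx[j], agents$hy[j]), -u, tj)
        agents$hx[j] <- h[1]; agents$hy[j] <- h[2]
        agents$persist[j] <- params$cil_persist
      }
    }
  }
  # 3. co-attraction (computed simultaneously, then applied)
  if (eps > 0 && n > 1) {
    disp <- t(vapply(seq_len(n), function(i)
      coattraction_displacement(agents[i, ], agents[-i, ], params),
      numeric(2)))
    agents$x <- agents$x + disp[, 1]
    agents$y <- agents$y + disp[, 2]
  }
  # 4. volume exclusion
  if (n > 1) for (pass in seq_len(params$exclusion_passes)) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- c(agents$x[i] - agents$x[j], agents$y[i] - agents$y[j])
      len <- sqrt(sum(d^2))
      target <- agents$radius[i] + agents$radius[j]
      if (len >= target) next
      if (len < 1e-9) {
        ang <- runif(1, 0, 2 * pi)
        u <- c(cos(ang), sin(ang))
      } else u <- d / len
      push <- 0.5 * params$exclusion_strength * (target - len)
      agents$x[i] <- agents$x[i] + push * u[1]
      agents$y[i] <- agents$y[i] + push * u[2]
      agents$x[j] <- agents$x[j] - push * u[1]
      agents$y[j] <- agents$y[j] - push * u[2]
    }
  }
  # 5. heading noise (one draw per agent regardless of persistence state)
  z <- rnorm(n, 0, params$zeta)
  for (i in seq_len(n)) {
    if (agents$persist[i] > 0) {
      agents$persist[i] <- agents$persist[i] - 1L
    } else if (params$zeta > 0) {
      h <- c(cos(z[i]) * agents$hx[i] - sin(z[i]) * agents$hy[i],
             sin(z[i]) * agents$hx[i] + cos(z[i]) * agents$hy[i])
      h <- h / sqrt(sum(h^2))
      agents$hx[i] <- h[1]; agents$hy[i] <- h[2]
    }
  }
  # 6. reflective boundaries (walls act on the cell surface)
  for (i in seq_len(n)) {
    x0 <- agents$radius[i]; x1 <- arena_$width - agents$radius[i]
    y0 <- arena_$y_min + agents$radius[i]
    y1 <- arena_$y_max - agents$radius[i]
    for (k in 1:4) {
      if (agents$x[i] < x0) {
        agents$x[i] <- 2 * x0 - agents$x[i]
        agents$hx[i] <- abs(agents$hx[i])
      } else if (agents$x[i] > x1) {
        agents$x[i] <- 2 * x1 - agents$x[i]
        agents$hx[i] <- -abs(agents$hx[i])
      } else if (agents$y[i] < y0) {
        agents$y[i] <- 2 * y0 - agents$y[i]
        agents$hy[i] <- abs(agents$hy[i])
      } else if (agents$y[i] > y1) {
        agents$y[i] <- 2 * y1 - agents$y[i]
        agents$hy[i] <- -abs(agents$hy[i])
      } else break
    }
    if (!is.finite(agents$x[i]) || !is.finite(agents$y[i]))
      stop("non-finite position for agent ", i)
  }
  agents
}

#' Simulate a full chain trajectory
#'
#' Initialises the chain (see [init_chain()]) and runs the compiled
#' discrete-element loop for `n_steps` steps, recording every
#' `sample_every`-th frame. Fully reproducible from the inputs and the seed.
#'
#' @inheritParams init_chain
#' @param seed integer master seed.
#' @return a `tnc_trajectory` (see [trajectory()]).
#' @export
#' @examples
#' tr <- simulate_chain(composition_preset("1:3"), seed = 1)
#' dim(tr$positions)
simulate_chain <- function(comp, arena_ = arena(), params = model_params(),
                           seed = 1) {
  set.seed(seed)
  ag <- init_chain(comp, arena_, params, seed = NULL)
  theta_id <- resolve_level(params, "theta")
  eps <- resolve_level(params, "eps")
  mode_code <- match(params$cil_mode, c("off", "differential", "all_pairs")) - 1L
  res <- sim_core(cbind(ag$x, ag$y), cbind(ag$hx, ag$hy),
                  as.integer(ag$persist),
                  as.integer(ag$identity == "follower"), ag$radius, ag$speed,
                  unname(theta_id[ag$identity]), mode_code, eps,
                  params$coattraction_range, params$zeta, params$dt,
                  unname(params$cil_push_scale * theta_id[ag$identity]),
                  as.integer(isTRUE(params$cil_sustained)),
                  as.integer(params$n_steps), as.integer(params$sample_every),
                  as.integer(params$cil_persist), params$contact_tol,
                  as.integer(params$exclusion_passes),
                  params$exclusion_strength,
                  0, arena_$width, arena_$y_min, arena_$y_max)
  n_frames <- params$n_steps %/% params$sample_every + 1
  times <- (seq_len(n_frames) - 1) * params$dt * params$sample_every
  trajectory(array(res$positions, dim = c(n_frames, nrow(ag), 2)),
             identities = ag$identity, times = times, radius = ag$radius,
             params = params, arena_ = arena_, seed = seed)
}

#' Trajectory container
#'
#' Holds the sampled positions of one simulated (or constructed) chain:
#' a `[n_frames, n_cells, 2]` array in um, per-cell identities and radii,
#' and the frame times in minutes. Constructed directly by fixtures and by
#' [simulate_chain()].
#'
#' @param positions numeric array `[n_frames, n_cells, 2]`.
#' @param identities character vector of `"leader"`/`"follower"`.
#' @param times strictly increasing frame times (minutes), constant spacing.
#' @param radius per-cell radii (um); defaults derived from identity.
#' @param params,arena_,seed provenance (optional for fixtures).
#' @return an object of class `tnc_trajectory`.
#' @export
trajectory <- function(positions, identities, times = NULL, radius = NULL,
                       params = NULL, arena_ = NULL, seed = NULL) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 2)
  n <- dim(positions)[2]
  stopifnot(length(identities) == n)
  if (is.null(times)) times <- (seq_len(dim(positions)[1]) - 1) * 5
  stopifnot(length(times) == dim(positions)[1])
  if (dim(positions)[1] > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9)
      stop("times must be strictly increasing with constant spacing")
  }
  if (is.null(radius))
    radius <- ifelse(identities == "leader", 5.70, 4.79)
  structure(list(positions = positions, identities = identities,
                 times = times, radius = radius, params = params,
                 arena = arena_, seed = seed),
            class = "tnc_trajectory")
}

#' @export
print.tnc_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("tnc_trajectory: %d cells (%d leader), %d frames, %.0f min\n",
              d[2], sum(x$identities == "leader"), d[1], max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.tnc_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  data.frame(
    cell_id = rep(seq_len(d[2]), each = d[1]),
    identity = rep(x$identities, each = d[1]),
    frame = rep(seq_len(d[1]) - 1L, d[2]),
    t_min = rep(x$times, d[2]),
    x_um = as.vector(x$positions[, , 1]),
    y_um = as.vector(x$positions[, , 2]),
    z_um = 0,
    stringsAsFactors = FALSE
  )
}
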