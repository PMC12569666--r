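# Sampling machinery: BAOAB Langevin dynamics with rigid-segment support,
# velocity-Verlet NVE (validation), slab construction, spherical confinement
# and temperature-ladder exchange.

#' Integrator settings
#'
#' @param timestep Integration step, ps (default 0.01 ps = 10 fs).
#' @param temperature Thermostat temperature, K.
#' @param damping Langevin damping time constant, ps; the friction force is
#'   `-(m / damping) * v` (LAMMPS convention). 1000 ps for slab
#'   phase-coexistence runs, 1 ps for replica-exchange-style runs.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param output_stride Steps between stored frames (default the equivalent
#'   of 100 ps).
#' @return An `integrator_config` list.
#' @export
integrator_config <- function(timestep = 0.01, temperature = 300,
                              damping = 1000, seed = NULL,
                              output_stride = round(100 / timestep)) {
  stopifnot(timestep > 0, temperature > 0, damping > 0, output_stride >= 1)
  structure(list(timestep = timestep, temperature = temperature,
                 damping = damping, seed = seed,
                 output_stride = as.integer(output_stride)),
            class = "integrator_config")
}

# --- rigid-body helpers -----------------------------------------------------

.rodrigues <- function(omega, dt) {
  th <- sqrt(sum(omega^2)) * dt
  if (th < 1e-12) return(diag(3))
  k <- omega / sqrt(sum(omega^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.make_body <- function(idx, positions, masses) {
  m <- masses[idx]
  com <- colSums(positions[idx, , drop = FALSE] * m) / sum(m)
  rel <- sweep(positions[idx, , drop = FALSE], 2, com)
  I <- matrix(0, 3, 3)
  for (k in seq_along(idx)) {
    r <- rel[k, ]
    I <- I + m[k] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  ev <- eigen(I, symmetric = TRUE)
  # body frame = principal frame; world rotation starts at the eigenbasis
  R <- ev$vectors
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(idx = idx, mass = sum(m), m_beads = m,
       body_coords = rel %*% R,          # coordinates in principal frame
       Ip = pmax(ev$values, 0),          # principal moments, amu nm^2
       R = R, com = com, vcom = c(0, 0, 0), omega = c(0, 0, 0))
}

.body_positions <- function(body) {
  sweep(body$body_coords %*% t(body$R), 2, body$com, "+")
}

# --- state ------------------------------------------------------------------

#' Create a dynamical state
#'
#' Bundles positions, velocities and rigid-body bookkeeping. Rigid segments
#' declared in the topology are turned into rigid bodies: their beads move
#' as one unit (centre-of-mass translation plus rotation about it), so
#' intra-segment distances are preserved exactly by construction.
#'
#' @param topology A `cg_topology`.
#' @param positions N x 3 matrix, nm.
#' @param velocities Optional N x 3 matrix, nm/ps; if `NULL` and
#'   `temperature` given, drawn from the Maxwell-Boltzmann distribution,
#'   else zero.
#' @param temperature Temperature for velocity initialisation, K.
#' @return A `cg_state`.
#' @export
init_state <- function(topology, positions, velocities = NULL,
                       temperature = NULL) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == topology$n_beads, ncol(positions) == 3)
  if (is.null(velocities)) {
    velocities <- matrix(0, topology$n_beads, 3)
    if (!is.null(temperature)) {
      sd_v <- sqrt(cg_constants$kB * temperature * cg_constants$acc_unit /
                     topology$mass)
      velocities <- matrix(rnorm(3 * topology$n_beads), ncol = 3) * sd_v
    }
  }
  bodies <- lapply(topology$rigid, .make_body, positions = positions,
                   masses = topology$mass)
  # snap rigid beads onto the exact rigid representation
  for (b in bodies) positions[b$idx, ] <- .body_positions(b)
  structure(list(positions = positions, velocities = velocities,
                 bodies = bodies, time = 0, step = 0L),
            class = "cg_state")
}

#' @export
print.cg_state <- function(x, ...) {
  cat(sprintf("CG state: %d beads, %d rigid bodies, t = %g ps\n",
              nrow(x$positions), length(x$bodies), x$time))
  invisible(x)
}

.free_beads <- function(topology) {
  rigid <- unlist(topology$rigid, use.names = FALSE)
  setdiff(seq_len(topology$n_beads), rigid)
}

.wrap_state <- function(state, geometry) {
  if (geometry$kind != "box") return(state)
  L <- geometry$L
  pos <- state$positions
  if (length(state$bodies)) {
    in_body <- unlist(lapply(state$bodies, `[[`, "idx"), use.names = FALSE)
    free <- setdiff(seq_len(nrow(pos)), in_body)
  } else free <- seq_len(nrow(pos))
  for (k in 1:3)
    pos[free, k] <- pos[free, k] - L[k] * floor(pos[free, k] / L[k])
  # wrap bodies by whole-body shifts so rigidity is untouched
  for (bi in seq_along(state$bodies)) {
    b <- state$bodies[[bi]]
    shift <- -L * floor(b$com / L)
    if (any(shift != 0)) {
      state$bodies[[bi]]$com <- b$com + shift
      pos[b$idx, ] <- sweep(pos[b$idx, , drop = FALSE], 2, shift, "+")
    }
  }
  state$positions <- pos
  state
}

# core BAOAB sweep shared by langevin_step() and run_langevin()
.run_baoab <- function(state, topology, table, config, n_steps, ff,
                       record = FALSE) {
  dt <- config$timestep
  kT <- cg_constants$kB * config$temperature * cg_constants$acc_unit # amu nm^2/ps^2
  acc <- cg_constants$acc_unit
  free <- .free_beads(topology)
  m_free <- topology$mass[free]
  c1 <- exp(-dt / config$damping)
  c2 <- sqrt(1 - c1^2)
  sd_free <- sqrt(kT / m_free)
  pos <- state$positions
  vel <- state$velocities
  bodies <- state$bodies
  nb <- length(bodies)
  frames <- if (record) vector("list", n_steps %/% config$output_stride)
  nf <- 0L
  geometry <- topology$geometry

  eval_ff <- ff(pos)
  F <- eval_ff$forces

  body_kick <- function(b, Fm, h) {
    Ft <- colSums(Fm[b$idx, , drop = FALSE])
    rel <- sweep(pos[b$idx, , drop = FALSE], 2, b$com)
    tau <- colSums(cbind(
      rel[, 2] * Fm[b$idx, 3] - rel[, 3] * Fm[b$idx, 2],
      rel[, 3] * Fm[b$idx, 1] - rel[, 1] * Fm[b$idx, 3],
      rel[, 1] * Fm[b$idx, 2] - rel[, 2] * Fm[b$idx, 1]))
    b$vcom <- b$vcom + h * Ft * acc / b$mass
    Iw_inv <- b$R %*% diag(ifelse(b$Ip > 1e-10, 1 / pmax(b$Ip, 1e-10), 0)) %*%
      t(b$R)
    b$omega <- b$omega + h * as.vector(Iw_inv %*% tau) * acc
    b
  }
  body_drift <- function(b, h) {
    b$com <- b$com + h * b$vcom
    b$R <- .rodrigues(b$omega, h) %*% b$R
    b
  }

  for (s in seq_len(n_steps)) {
    # B
    vel[free, ] <- vel[free, , drop = FALSE] +
      (0.5 * dt * acc / m_free) * F[free, , drop = FALSE]
    if (nb) bodies <- lapply(bodies, body_kick, Fm = F, h = 0.5 * dt)
    # A
    pos[free, ] <- pos[free, , drop = FALSE] +
      0.5 * dt * vel[free, , drop = FALSE]
    if (nb) {
      bodies <- lapply(bodies, body_drift, h = 0.5 * dt)
      for (b in bodies) pos[b$idx, ] <- .body_positions(b)
    }
    # O
    vel[free, ] <- c1 * vel[free, , drop = FALSE] +
      c2 * sd_free * matrix(rnorm(3 * length(free)), ncol = 3)
    if (nb) bodies <- lapply(bodies, function(b) {
      b$vcom <- c1 * b$vcom + c2 * sqrt(kT / b$mass) * rnorm(3)
      wb <- as.vector(t(b$R) %*% b$omega)
      ok <- b$Ip > 1e-10
      wb[ok] <- c1 * wb[ok] + c2 * sqrt(kT / b$Ip[ok]) * rnorm(sum(ok))
      wb[!ok] <- 0
      b$omega <- as.vector(b$R %*% wb)
      b
    })
    # A
    pos[free, ] <- pos[free, , drop = FALSE] +
      0.5 * dt * vel[free, , drop = FALSE]
    if (nb) {
      bodies <- lapply(bodies, body_drift, h = 0.5 * dt)
      for (b in bodies) pos[b$idx, ] <- .body_positions(b)
    }
    if (anyNA(pos) || any(!is.finite(pos)))
      stop("integration blow-up: non-finite coordinates at step ",
           state$step + s)
    # B with fresh forces
    eval_ff <- ff(pos)
    F <- eval_ff$forces
    vel[free, ] <- vel[free, , drop = FALSE] +
      (0.5 * dt * acc / m_free) * F[free, , drop = FALSE]
    if (nb) bodies <- lapply(bodies, body_kick, Fm = F, h = 0.5 * dt)

    if (record && s %% config$output_stride == 0L) {
      nf <- nf + 1L
      frames[[nf]] <- list(time = state$time + s * dt, positions = pos,
                           box = geometry)
    }
  }
  state$positions <- pos
  state$velocities <- vel
  state$bodies <- bodies
  state$time <- state$time + n_steps * dt
  state$step <- state$step + n_steps
  state <- .wrap_state(state, geometry)
  list(state = state, frames = if (record) frames[seq_len(nf)])
}

#' Advance a state by Langevin dynamics
#'
#' BAOAB splitting of underdamped Langevin dynamics at the configured
#' temperature; friction per bead is `m / damping` (so the velocity
#' relaxation time equals `damping`). Rigid segments translate and rotate as
#' rigid bodies driven by the net force and torque on their beads, with the
#' same thermostat applied to their centre-of-mass and angular velocities.
#' Periodic wrapping is applied in box geometry. Runs are deterministic for
#' a fixed `config$seed`.
#'
#' @param state A `cg_state`.
#' @param topology,table System definition and [hps_table()].
#' @param config An [integrator_config()]; `config$seed`, when non-`NULL`,
#'   seeds the RNG before the first step.
#' @param n_steps Number of steps to take.
#' @param ff Optional evaluator from [make_energy_force()] (rebuilt when
#'   omitted).
#' @param cutoff Nonbonded truncation, nm.
#' @return The advanced `cg_state`.
#' @export
langevin_step <- function(state, topology, table, config, n_steps = 1,
                          ff = NULL, cutoff = 3.5) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(ff)) ff <- make_energy_force(topology, table, cutoff)
  .run_baoab(state, topology, table, config, n_steps, ff)$state
}

#' Run Langevin dynamics and record a trajectory
#'
#' @inheritParams langevin_step
#' @param n_steps Total steps.
#' @return A list with `trajectory` (a `cg_trajectory`, frames every
#'   `config$output_stride` steps) and `state` (final state).
#' @export
run_langevin <- function(state, topology, table, config, n_steps,
                         ff = NULL, cutoff = 3.5) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(ff)) ff <- make_energy_force(topology, table, cutoff)
  out <- .run_baoab(state, topology, table, config, n_steps, ff,
                    record = TRUE)
  list(trajectory = new_trajectory(out$frames, topology), state = out$state)
}

#' Velocity-Verlet run without thermostat (validation integrator)
#'
#' Microcanonical integration used to certify force correctness through
#' energy conservation; it is not part of the production sampling protocol.
#'
#' @inheritParams langevin_step
#' @param dt Timestep, ps.
#' @param record_stride Steps between recorded energy/frame samples.
#' @param include Term subset passed to [make_energy_force()].
#' @return List with `state`, `trajectory` and `energies` (data frame with
#'   `time`, `kinetic`, `potential`, `total` in kcal/mol).
#' @export
run_nve <- function(state, topology, table, dt = 0.01, n_steps = 1000,
                    record_stride = 10, cutoff = 3.5,
                    include = c("bond", "vdw", "elec", "crowder", "wall")) {
  ff <- make_energy_force(topology, table, cutoff, include = include)
  acc <- cg_constants$acc_unit
  free <- .free_beads(topology)
  m_free <- topology$mass[free]
  pos <- state$positions
  vel <- state$velocities
  geometry <- topology$geometry
  ev <- ff(pos)
  F <- ev$forces
  n_rec <- n_steps %/% record_stride
  en <- matrix(NA_real_, n_rec + 1L, 4L)
  frames <- vector("list", n_rec)
  ke0 <- .kinetic_energy(vel, topology$mass)
  en[1L, ] <- c(state$time, ke0, ev$energy$total, ke0 + ev$energy$total)
  r <- 1L
  for (s in seq_len(n_steps)) {
    vel[free, ] <- vel[free, , drop = FALSE] +
      (0.5 * dt * acc / m_free) * F[free, , drop = FALSE]
    pos[free, ] <- pos[free, , drop = FALSE] + dt * vel[free, , drop = FALSE]
    if (any(!is.finite(pos)))
      stop("integration blow-up: non-finite coordinates at step ", s)
    ev <- ff(pos)
    F <- ev$forces
    vel[free, ] <- vel[free, , drop = FALSE] +
      (0.5 * dt * acc / m_free) * F[free, , drop = FALSE]
    if (s %% record_stride == 0L) {
      r <- r + 1L
      ke <- .kinetic_energy(vel, topology$mass)
      en[r, ] <- c(state$time + s * dt, ke, ev$energy$total,
                   ke + ev$energy$total)
      frames[[r - 1L]] <- list(time = state$time + s * dt, positions = pos,
                               box = geometry)
    }
  }
  state$positions <- pos
  state$velocities <- vel
  state$time <- state$time + n_steps * dt
  state$step <- state$step + n_steps
  energies <- as.data.frame(en)
  names(energies) <- c("time", "kinetic", "potential", "total")
  list(state = state, trajectory = new_trajectory(frames, topology),
       energies = energies)
}

#' Harmonic spherical confinement force
#'
#' Zero inside the confinement radius; beyond it, an inward restoring force
#' of magnitude `k_wall * (|r| - radius)`.
#'
#' @param positions N x 3 matrix (or length-3 vector), nm, relative to the
#'   confinement centre.
#' @param radius Confinement radius, nm.
#' @param k_wall Wall stiffness, kcal/(mol nm^2).
#' @return N x 3 force matrix, kcal/(mol nm).
#' @export
spherical_confinement_force <- function(positions, radius, k_wall = 10) {
  if (radius <= 0) stop("radius must be positive")
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  F <- matrix(0, nrow(positions), 3)
  rad <- sqrt(rowSums(positions^2))
  out <- rad > radius
  if (any(out))
    F[out, ] <- -k_wall * (rad[out] - radius) / rad[out] *
      positions[out, , drop = FALSE]
  F
}

# --- slab construction ------------------------------------------------------

#' Slab-protocol settings
#'
#' Phase-coexistence initialisation: chains are packed into a cube, the cube
#' is compressed by interleaved affine rescaling and damped relaxation
#' (standing in for a short high-pressure NPT run), and the box is then
#' elongated along z so the dense slab coexists with dilute vapour.
#'
#' @param target_cube Edge of the compressed cube, nm.
#' @param elongated_Lz Final box length along z, nm.
#' @param start_factor Initial cube edge as a multiple of `target_cube`.
#' @param scale_step Affine contraction factor per compression cycle.
#' @param relax_steps Damped Langevin steps between contractions.
#' @param max_place_tries Placement retries per chain before giving up.
#' @return A `slab_protocol` list.
#' @export
slab_protocol <- function(target_cube = 15, elongated_Lz = 50,
                          start_factor = 1.6, scale_step = 0.95,
                          relax_steps = 25, max_place_tries = 200) {
  stopifnot(elongated_Lz > target_cube, start_factor >= 1,
            scale_step > 0, scale_step < 1)
  structure(list(target_cube = target_cube, elongated_Lz = elongated_Lz,
                 start_factor = start_factor, scale_step = scale_step,
                 relax_steps = relax_steps,
                 max_place_tries = max_place_tries),
            class = "slab_protocol")
}

# random-walk chain inside a cube, fixed bond length, soft clash avoidance
.place_chain <- function(n, r0, L, existing, min_dist, max_tries) {
  for (try in seq_len(max_tries)) {
    pos <- matrix(NA_real_, n, 3)
    pos[1, ] <- runif(3, 0.1 * L, 0.9 * L)
    ok <- TRUE
    for (k in seq_len(n - 1)) {
      placed <- FALSE
      for (a in 1:20) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- pos[k, ] + r0 * u
        if (any(cand < 0.05 * L) || any(cand > 0.95 * L)) next
        prev <- pos[seq_len(max(1, k - 1)), , drop = FALSE]
        d2 <- min(rowSums(sweep(prev, 2, cand)^2))
        de <- if (nrow(existing)) min(rowSums(sweep(existing, 2, cand)^2))
              else Inf
        if (d2 > (0.7 * min_dist)^2 && de > min_dist^2) {
          pos[k + 1, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  NULL
}

#' Build a phase-coexistence slab state
#'
#' Randomly places the topology's chains inside a cube, compresses the cube
#' to `protocol$target_cube` by stepwise isotropic rescaling interleaved
#' with short damped Langevin relaxations, then elongates the box along z
#' (keeping coordinates, slab centred at Lz/2) and scatters any crowders
#' through the elongated box. The topology's geometry must be a periodic box
#' whose x/y edges give the cube and whose Lz is the elongated length.
#'
#' @param topology A `cg_topology` with box geometry.
#' @param protocol A [slab_protocol()].
#' @param table An [hps_table()].
#' @param config An [integrator_config()] used for the relaxation
#'   interleaves (its seed seeds the whole construction).
#' @return A `cg_state` ready for NVT relaxation in the elongated box.
#' @export
build_slab <- function(topology, protocol, table, config) {
  geometry <- topology$geometry
  if (geometry$kind != "box") stop("slab construction needs a periodic box")
  if (!is.null(config$seed)) set.seed(config$seed)
  L0 <- protocol$target_cube * protocol$start_factor
  lens <- topology$chain_lengths
  placed <- matrix(numeric(0), 0, 3)
  chains <- vector("list", length(lens))
  for (k in seq_along(lens)) {
    pos <- .place_chain(lens[k], table$r0, L0, placed, min_dist = 0.5,
                        max_tries = protocol$max_place_tries)
    if (is.null(pos))
      stop("chain placement failed after ", protocol$max_place_tries,
           " tries; use a larger box or fewer chains")
    chains[[k]] <- pos
    placed <- rbind(placed, pos)
  }
  n_crowd <- sum(topology$is_crowder)
  # compress the protein cube first, without crowders
  prot_topo <- topology
  if (n_crowd) {
    prot_topo <- build_topology(
      sequences = .topology_sequences(topology), table = table,
      geometry = geometry_box(L0, L0, L0),
      rigid_ranges = NULL, regions = topology$regions)
    prot_topo$rigid <- topology$rigid
  } else {
    prot_topo$geometry <- geometry_box(L0, L0, L0)
  }
  state <- init_state(prot_topo, placed, temperature = config$temperature)
  relax_cfg <- integrator_config(timestep = config$timestep,
                                 temperature = config$temperature,
                                 damping = min(config$damping, 1),
                                 output_stride = 1e6)
  L <- L0
  while (L > protocol$target_cube) {
    Lnew <- max(L * protocol$scale_step, protocol$target_cube)
    f <- Lnew / L
    state$positions <- state$positions * f
    for (bi in seq_along(state$bodies)) {
      state$bodies[[bi]]$com <- state$bodies[[bi]]$com * f
      state$positions[state$bodies[[bi]]$idx, ] <-
        .body_positions(state$bodies[[bi]])
    }
    L <- Lnew
    prot_topo$geometry <- geometry_box(L, L, L)
    ff <- make_energy_force(prot_topo, table)
    state <- .run_baoab(state, prot_topo, table, relax_cfg,
                        protocol$relax_steps, ff)$state
  }
  # elongate along z: keep coordinates, centre slab at Lz/2
  Lz <- protocol$elongated_Lz
  shift <- (Lz - L) / 2
  state$positions[, 3] <- state$positions[, 3] + shift
  for (bi in seq_along(state$bodies))
    state$bodies[[bi]]$com[3] <- state$bodies[[bi]]$com[3] + shift
  prot_pos <- state$positions
  # scatter crowders through the elongated box, avoiding the protein core
  crowd_pos <- matrix(numeric(0), 0, 3)
  if (n_crowd) {
    spec <- topology$crowder
    min2 <- (spec$delta_pc + 0.15)^2
    minc2 <- (spec$delta_cc + 0.15)^2
    tries <- 0
    while (nrow(crowd_pos) < n_crowd) {
      cand <- c(runif(1, 0, L), runif(1, 0, L), runif(1, 0, Lz))
      dp <- min(rowSums(sweep(prot_pos, 2, cand)^2))
      dc <- if (nrow(crowd_pos))
        min(rowSums(sweep(crowd_pos, 2, cand)^2)) else Inf
      if (dp > min2 && dc > minc2) crowd_pos <- rbind(crowd_pos, cand)
      tries <- tries + 1
      if (tries > 500 * n_crowd)
        stop("crowder placement failed; lower the volume fraction")
    }
  }
  full_topo <- topology
  full_topo$geometry <- geometry_box(L, L, Lz)
  all_pos <- rbind(prot_pos, crowd_pos)
  out <- init_state(full_topo, all_pos, temperature = config$temperature)
  out
}

.topology_sequences <- function(topology) {
  vapply(seq_len(topology$n_chains), function(k)
    paste(topology$code[chain_beads(topology, k)], collapse = ""),
    character(1))
}

# --- temperature-ladder exchange --------------------------------------------

#' Temperature-ladder settings
#'
#' @param temperatures Strictly increasing replica temperatures, K. The
#'   production-scale protocol uses 32 replicas spanning 150-800 K; desk
#'   runs use a handful over a narrow band.
#' @param exchange_stride Time between exchange attempts, ps.
#' @param seed Integer RNG seed.
#' @return A `ladder_config` list.
#' @export
ladder_config <- function(temperatures, exchange_stride = 10, seed = NULL) {
  if (length(temperatures) < 2 || any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing (>= 2 replicas)")
  structure(list(temperatures = temperatures,
                 exchange_stride = exchange_stride, seed = seed),
            class = "ladder_config")
}

#' Attempt neighbour swaps on a temperature ladder
#'
#' Metropolis replica exchange between neighbouring temperatures: a swap of
#' configurations between replicas i (colder) and j = i+1 is accepted with
#' probability `min(1, exp((beta_i - beta_j) * (U_i - U_j)))`. Even- and
#' odd-offset neighbour pairs alternate between sweeps. On acceptance the
#' states are exchanged and their velocities rescaled by
#' `sqrt(T_new / T_old)`.
#'
#' @param states List of `cg_state` objects, one per temperature.
#' @param energies Numeric vector of potential energies, kcal/mol.
#' @param ladder A [ladder_config()].
#' @param sweep Sweep counter selecting the pairing offset (odd sweeps pair
#'   (1,2), (3,4), ...; even sweeps pair (2,3), (4,5), ...).
#' @return List with `states`, `energies` (both possibly permuted),
#'   `attempted` and `accepted` (per-pair logical vectors indexed by the
#'   colder replica).
#' @export
ladder_exchange <- function(states, energies, ladder, sweep = 1) {
  nT <- length(ladder$temperatures)
  if (length(states) != nT || length(energies) != nT)
    stop("need one state and one energy per ladder temperature")
  beta <- 1 / (cg_constants$kB * ladder$temperatures)
  first <- if (sweep %% 2 == 1) 1L else 2L
  lo <- seq(first, nT - 1L, by = 2L)
  attempted <- rep(FALSE, nT - 1L)
  accepted <- rep(FALSE, nT - 1L)
  for (i in lo) {
    j <- i + 1L
    attempted[i] <- TRUE
    p <- min(1, exp((beta[i] - beta[j]) * (energies[i] - energies[j])))
    if (runif(1) < p) {
      accepted[i] <- TRUE
      si <- states[[i]]; sj <- states[[j]]
      scale_up <- sqrt(ladder$temperatures[i] / ladder$temperatures[j])
      sj$velocities <- sj$velocities * scale_up
      si$velocities <- si$velocities / scale_up
      states[[i]] <- sj; states[[j]] <- si
      energies[c(i, j)] <- energies[c(j, i)]
    }
  }
  list(states = states, energies = energies, attempted = attempted,
       accepted = accepted)
}
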