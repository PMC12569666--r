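# Seeded synthetic-trajectory generators with analytic answer keys. They
# emulate statistical structure (Brownian motion, exponential correlations,
# slab-shaped density fields, countable contacts, prescribed orientations),
# not force-field physics, so every analysis stage can be validated without
# long simulations.

# minimal single-bead-species topology used by fixtures
.fixture_topology <- function(n_chains, chain_len, geometry,
                              n_crowders = 0, sigma = 0.6, mass = 100,
                              regions = NULL) {
  tab <- hps_table(data.frame(code = "X", mass = mass, sigma = sigma,
                              lambda0 = 0.5, charge = 0L))
  topo <- build_topology(rep(strrep("X", chain_len), n_chains), tab,
                         geometry, regions = regions)
  if (n_crowders > 0) {
    cs <- crowder_spec("repulsive")
    topo$n_beads <- topo$n_beads + n_crowders
    topo$chain <- c(topo$chain, rep(NA_integer_, n_crowders))
    topo$local_index <- c(topo$local_index, rep(NA_integer_, n_crowders))
    topo$code <- c(topo$code, rep(NA_character_, n_crowders))
    topo$mass <- c(topo$mass, rep(cs$mass, n_crowders))
    topo$sigma <- c(topo$sigma, rep(2 * cs$r_c, n_crowders))
    topo$lambda0 <- c(topo$lambda0, rep(0, n_crowders))
    topo$charge <- c(topo$charge, rep(0L, n_crowders))
    topo$is_crowder <- c(topo$is_crowder, rep(TRUE, n_crowders))
    topo$crowder <- cs
  }
  topo
}

#' Ideal Brownian trajectories with known diffusion coefficient
#'
#' Independent 3D Gaussian increments with variance `2 D dt` per axis for
#' each of `n_particles` single-bead chains, so the z-MSD is exactly
#' `2 D dt^1` in expectation.
#'
#' @param D Diffusion coefficient, nm^2/ps.
#' @param n_frames Number of stored frames.
#' @param dt Frame spacing, ps.
#' @param seed Integer seed.
#' @param n_particles Number of independent walkers (one-bead chains).
#' @param box Optional [geometry_box()]; default a huge open-box stand-in.
#' @return List: `trajectory` (a `cg_trajectory`) and `key`
#'   (`list(D, alpha = 1)`).
#' @export
gen_brownian <- function(D, n_frames, dt = 1, seed = 1, n_particles = 1,
                         box = NULL) {
  if (D < 0) stop("D must be non-negative")
  set.seed(seed)
  if (is.null(box)) box <- geometry_box(1e6, 1e6, 1e6)
  topo <- .fixture_topology(n_particles, 1L, box)
  start <- matrix(runif(3 * n_particles, 0.45, 0.55) * min(box$L),
                  n_particles, 3)
  sd_step <- sqrt(2 * D * dt)
  frames <- vector("list", n_frames)
  pos <- start
  for (k in seq_len(n_frames)) {
    frames[[k]] <- list(time = (k - 1) * dt, positions = pos, box = box)
    pos <- pos + matrix(rnorm(3 * n_particles, sd = sd_step),
                        n_particles, 3)
  }
  list(trajectory = new_trajectory(frames, topo),
       key = list(D = D, alpha = 1))
}

#' Ornstein-Uhlenbeck series with known correlation time
#'
#' Exact discretisation `x[k+1] = mean + phi (x[k] - mean) +
#' sd sqrt(1 - phi^2) xi` with `phi = exp(-dt / tau)`, whose stationary
#' autocorrelation is exactly `exp(-lag / tau)`.
#'
#' @param tau Correlation time, ps.
#' @param mean,sd Stationary mean and standard deviation.
#' @param n Series length.
#' @param dt Sampling interval, ps.
#' @param seed Integer seed.
#' @return List: `series` (numeric), `dt`, and `key`
#'   (`list(tau, acf = function(lag))`).
#' @export
gen_ou_series <- function(tau, mean = 0, sd = 1, n = 1000, dt = 1,
                          seed = 1) {
  if (tau <= 0 || sd <= 0) stop("tau and sd must be positive")
  set.seed(seed)
  phi <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- mean + sd * rnorm(1)
  innov <- sd * sqrt(1 - phi^2) * rnorm(n - 1)
  for (k in 2:n) x[k] <- mean + phi * (x[k - 1] - mean) + innov[k - 1]
  list(series = x, dt = dt,
       key = list(tau = tau, acf = function(lag) exp(-lag / tau)))
}

#' Slab configuration with a tanh interface of known plateau density
#'
#' Places `n_beads` single-bead chains with z drawn from a density
#' proportional to `1 + tanh((z0 - |z - Lz/2|) / width)` (uniform in x, y).
#' The half-thickness `z0` is solved so the plateau number density equals
#' the requested value exactly; the analytic 0.2/0.8-of-maximum crossings
#' sit at `z0 +/- width * atanh(0.6)` from the centre.
#'
#' @param plateau Target core number density, beads/nm^3.
#' @param width Interface width, nm.
#' @param box A [geometry_box()].
#' @param n_beads Number of beads.
#' @param seed Integer seed.
#' @param n_frames Number of (independent) frames to draw.
#' @return List: `trajectory`, and `key` with `rho_h`, `z0`, the analytic
#'   crossing offsets `d_inner` (0.8 max) and `d_outer` (0.2 max) from the
#'   slab centre, and `width`.
#' @export
gen_tanh_slab <- function(plateau, width, box, n_beads, seed = 1,
                          n_frames = 1) {
  stopifnot(inherits(box, "cg_geometry"), box$kind == "box")
  L <- box$L; Lz <- L[3]
  area <- L[1] * L[2]
  shape <- function(z, z0) 1 + tanh((z0 - abs(z - Lz / 2)) / width)
  # solve z0 so that plateau * area * integral(shape)/2 == n_beads
  target <- function(z0) {
    I <- integrate(shape, 0, Lz, z0 = z0, rel.tol = 1e-10)$value
    plateau * area * I / 2 - n_beads
  }
  hi <- Lz / 2 - 1e-6
  if (target(hi) < 0)
    stop("plateau * volume too small to hold n_beads: enlarge the box or ",
         "lower n_beads")
  z0 <- uniroot(target, c(1e-6, hi), tol = 1e-10)$root
  set.seed(seed)
  # inverse-CDF sampling on a fine grid
  zg <- seq(0, Lz, length.out = 4096)
  pdf <- shape(zg, z0)
  cdf <- cumsum(pdf); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  topo <- .fixture_topology(n_beads, 1L, box)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    z <- approx(cdf, zg, runif(n_beads), ties = "ordered")$y
    frames[[k]] <- list(time = k - 1,
                        positions = cbind(runif(n_beads, 0, L[1]),
                                          runif(n_beads, 0, L[2]), z),
                        box = box)
  }
  datanh <- atanh(0.6)
  list(trajectory = new_trajectory(frames, topo),
       key = list(rho_h = plateau, z0 = z0, width = width,
                  d_inner = z0 - width * datanh,
                  d_outer = z0 + width * datanh))
}

#' Uniform ideal-gas configurations
#'
#' Uniform random beads (optionally flagged as crowders) in a box or
#' sphere; the answer key is the bulk number density.
#'
#' @param n Number of beads.
#' @param geometry A [geometry_box()] or [geometry_sphere()].
#' @param seed Integer seed.
#' @param n_frames Independent frames.
#' @param as_crowders Flag the beads as crowders (a single protein bead is
#'   then pinned at the centre so crowder-centric analyses have a
#'   reference).
#' @return List: `trajectory`, `key = list(density)`.
#' @export
gen_ideal_gas <- function(n, geometry, seed = 1, n_frames = 1,
                          as_crowders = FALSE) {
  set.seed(seed)
  draw <- function(m) {
    if (geometry$kind == "box")
      cbind(runif(m, 0, geometry$L[1]), runif(m, 0, geometry$L[2]),
            runif(m, 0, geometry$L[3]))
    else {
      r <- geometry$radius * runif(m)^(1 / 3)
      u <- matrix(rnorm(3 * m), m, 3)
      u <- u / sqrt(rowSums(u^2))
      u * r
    }
  }
  if (as_crowders) {
    topo <- .fixture_topology(1L, 1L, geometry, n_crowders = n)
    center <- if (geometry$kind == "box") geometry$L / 2 else c(0, 0, 0)
    frames <- lapply(seq_len(n_frames), function(k)
      list(time = k - 1, positions = rbind(center, draw(n)),
           box = geometry))
  } else {
    topo <- .fixture_topology(n, 1L, geometry)
    frames <- lapply(seq_len(n_frames), function(k)
      list(time = k - 1, positions = draw(n), box = geometry))
  }
  list(trajectory = new_trajectory(frames, topo),
       key = list(density = n / .geometry_volume(geometry)))
}

#' Two-chain trajectory with an exactly countable contact schedule
#'
#' Lays two equal-length chains on widely separated parallel lines (no
#' incidental contacts) and, for each scheduled residue pair, moves the
#' partner residue to half the contact cutoff ("in") or twice the cutoff
#' ("out") frame by frame. The expected inter-chain contact map is emitted
#' exactly.
#'
#' @param n_frames Number of frames.
#' @param chain_len Residues per chain.
#' @param pattern List of `list(i, j, schedule)` entries: residue `i` of
#'   chain 1, residue `j` of chain 2, and a logical vector of length
#'   `n_frames` (in contact or not). Each `j` may appear at most once.
#' @param seed Integer seed (placement jitter only).
#' @param sigma Bead diameter used for the cutoff, nm.
#' @return List: `trajectory`, `key = list(contact_map)` (the exact
#'   `chain_len x chain_len` expected inter map).
#' @export
gen_contact_toy <- function(n_frames, chain_len = 10, pattern, seed = 1,
                            sigma = 0.6) {
  set.seed(seed)
  js <- vapply(pattern, `[[`, numeric(1), "j")
  if (anyDuplicated(js))
    stop("each chain-2 residue may appear in at most one pattern entry")
  spacing <- 10  # nm between consecutive beads and between chains
  box <- geometry_box(spacing * (chain_len + 2), 3 * spacing,
                      3 * spacing)
  topo <- .fixture_topology(2L, chain_len, box, sigma = sigma)
  base1 <- cbind((seq_len(chain_len)) * spacing, spacing, spacing)
  base2 <- cbind((seq_len(chain_len)) * spacing, 2 * spacing, spacing)
  r0 <- 0.75 * (sigma + sigma)
  expected <- matrix(0, chain_len, chain_len)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    p2 <- base2
    for (ent in pattern) {
      on <- ent$schedule[f]
      d <- if (on) 0.5 * r0 else 2 * r0
      p2[ent$j, ] <- base1[ent$i, ] + c(0, d, 0)
    }
    frames[[f]] <- list(time = f - 1, positions = rbind(base1, p2),
                        box = box)
  }
  for (ent in pattern)
    expected[ent$i, ent$j] <- mean(ent$schedule)
  # the inter map averages the two ordered chain pairs (1,2) and (2,1);
  # with the indicator symmetric in distance this symmetrises the matrix
  expected_sym <- (expected + t(expected)) / 2
  list(trajectory = new_trajectory(frames, topo),
       key = list(contact_map = expected_sym,
                  contact_map_12 = expected, cutoff = r0))
}

#' Chains with exactly prescribed segment orientations
#'
#' Builds one straight chain per requested `(phi, z)` pair, oriented so the
#' half-selection rule of [segment_orientation()] recovers exactly the
#' requested angle regardless of which residues are drawn. All three
#' regions of each chain share the direction.
#'
#' @param angles Orientation angles, degrees in `[0, 180]`.
#' @param z_positions Segment centre z-positions, nm (recycled).
#' @param chain_len Residues per chain.
#' @param box A [geometry_box()].
#' @param spacing Bead spacing along the direction, nm.
#' @param seed Integer seed (azimuths).
#' @return List: `trajectory`, `key` (data frame of requested `phi`, `z`).
#' @export
gen_helix_fan <- function(angles, z_positions, chain_len = 12,
                          box = geometry_box(50, 50, 50), spacing = 0.38,
                          seed = 1) {
  if (any(angles < 0 | angles > 180)) stop("angles must be in [0, 180]")
  set.seed(seed)
  z_positions <- rep(z_positions, length.out = length(angles))
  n <- length(angles)
  topo <- .fixture_topology(n, chain_len, box)
  pos <- matrix(0, n * chain_len, 3)
  for (k in seq_len(n)) {
    phi <- angles[k] * pi / 180
    az <- runif(1, 0, 2 * pi)
    dirv <- c(sin(phi) * cos(az), sin(phi) * sin(az), cos(phi))
    # bead index increasing along -dirv: the selection rule draws the base
    # from the second half and the tip from the first half (reverse sense),
    # so tip - base is a positive multiple of dirv for any drawn pair
    center <- c(box$L[1] * (k - 0.5) / n, box$L[2] / 2, z_positions[k])
    offs <- (seq_len(chain_len) - (chain_len + 1) / 2) * spacing
    pos[(k - 1) * chain_len + seq_len(chain_len), ] <-
      sweep(outer(-offs, dirv), 2, center, "+")
  }
  frames <- list(list(time = 0, positions = pos, box = box))
  list(trajectory = new_trajectory(frames, topo),
       key = data.frame(chain = seq_len(n), phi = angles,
                        z = z_positions))
}
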