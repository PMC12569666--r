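# Condensate observables: Rg, z-density profiles and dense-phase density,
# crowder RDF and internal/external classification, MSD and diffusion fits,
# contact maps, region contact numbers, contact-relaxation times, and
# segment-orientation maps.

# --- radius of gyration -----------------------------------------------------

#' Radius of gyration of one chain
#'
#' Mass-weighted Rg, `sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`, after
#' unwrapping the chain across periodic images.
#'
#' @param frame A single trajectory frame (`list(time, positions, box)`) or
#'   an N x 3 positions matrix.
#' @param topology A `cg_topology`.
#' @param chain Chain index.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, topology, chain = 1) {
  pos <- if (is.list(frame)) frame$positions else frame
  idx <- chain_beads(topology, chain)
  if (!length(idx)) stop("chain ", chain, " has no beads")
  m <- topology$mass[idx]
  if (sum(m) <= 0) stop("zero-mass chain")
  p <- .unwrap_chain(pos[idx, , drop = FALSE], topology$geometry)
  com <- colSums(p * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(p, 2, com)^2)) / sum(m))
}

#' Mean radius of gyration over a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @param chains Chain indices (default all).
#' @param t_init Equilibration time discarded from the average, ps.
#' @return Mean Rg, nm.
#' @export
rg_mean <- function(traj, chains = seq_len(traj$topology$n_chains),
                    t_init = 0) {
  frames <- .analysis_frames(traj, t_init)
  mean(vapply(frames, function(f)
    mean(vapply(chains, function(ch)
      radius_of_gyration(f, traj$topology, ch), numeric(1))), numeric(1)))
}

# --- density profile --------------------------------------------------------

# z-shift that puts the protein centre of mass at Lz/2, computed with the
# circular mean so condensates spanning the periodic boundary recentre
# correctly
.recenter_shift <- function(z, mass, Lz) {
  th <- 2 * pi * z / Lz
  zc <- (Lz / (2 * pi)) * atan2(sum(mass * sin(th)), sum(mass * cos(th)))
  zc <- zc %% Lz
  Lz / 2 - zc
}

.band_crossings <- function(z, dens, dmax, zc, side) {
  half <- if (side == "left") which(z <= zc) else which(z >= zc)
  zs <- z[half]; ds <- dens[half]
  if (side == "left") { ord <- order(zs, decreasing = TRUE) }
  else { ord <- order(zs) }
  zs <- zs[ord]; ds <- ds[ord]  # ordered from the centre outwards
  cross <- function(level) {
    below <- which(ds <= level)
    if (!length(below)) return(NA_real_)
    k <- below[1]
    if (k == 1) return(zs[1])
    # linear interpolation between the last bin above and first below
    z1 <- zs[k - 1]; z2 <- zs[k]; d1 <- ds[k - 1]; d2 <- ds[k]
    if (d1 == d2) return(z2)
    z1 + (level - d1) * (z2 - z1) / (d2 - d1)
  }
  c(inner = unname(cross(0.8 * dmax)), outer = unname(cross(0.2 * dmax)))
}

#' z-density profile of a slab trajectory
#'
#' Histograms bead density along z after per-frame condensate recentring
#' (the protein centre of mass, computed via the circular mean, is shifted
#' to Lz/2). Reports the dense-phase core density `rho_h` as the mean
#' protein density over the central plateau window, and the surface bands
#' where the protein density falls between 0.2 and 0.8 of its maximum.
#'
#' @param traj A `cg_trajectory` with periodic-box geometry.
#' @param bin_width Bin width along z, nm.
#' @param weight `"mass"` (density in amu/nm^3) or `"count"` (beads/nm^3).
#' @param half_width Half-width of the central plateau window used for
#'   `rho_h`, nm; default a quarter of Lz.
#' @param t_init Equilibration discard, ps.
#' @param recenter Recentre each frame before histogramming.
#' @return A `density_profile` object: `z` (bin centres), `protein`,
#'   `crowder` (densities), `rho_h`, `surface_band` (data frame with
#'   columns `side`, `z_inner`, `z_outer`), plus bookkeeping fields.
#' @export
density_profile <- function(traj, bin_width = 0.5,
                            weight = c("mass", "count"), half_width = NULL,
                            t_init = 0, recenter = TRUE) {
  weight <- match.arg(weight)
  topo <- traj$topology
  if (topo$geometry$kind != "box")
    stop("density profiles need a periodic box")
  if (!any(!topo$is_crowder)) stop("no protein beads in topology")
  frames <- .analysis_frames(traj, t_init)
  L <- topo$geometry$L
  Lz <- L[3]
  if (is.null(half_width)) half_width <- 0.25 * Lz
  edges <- seq(0, Lz, by = bin_width)
  if (tail(edges, 1) < Lz) edges <- c(edges, Lz)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  prot <- !topo$is_crowder
  w <- if (weight == "mass") topo$mass else rep(1, topo$n_beads)
  area <- L[1] * L[2]
  widths <- diff(edges)
  acc_p <- numeric(nb); acc_c <- numeric(nb)
  for (f in frames) {
    z <- f$positions[, 3]
    if (recenter)
      z <- z + .recenter_shift(z[prot], topo$mass[prot], Lz)
    z <- z %% Lz
    bin <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L), nb)
    tp <- tapply(w[prot], factor(bin[prot], levels = seq_len(nb)), sum)
    acc_p <- acc_p + ifelse(is.na(tp), 0, tp)
    if (any(topo$is_crowder)) {
      tc <- tapply(w[topo$is_crowder],
                   factor(bin[topo$is_crowder], levels = seq_len(nb)), sum)
      acc_c <- acc_c + ifelse(is.na(tc), 0, tc)
    }
  }
  nfr <- length(frames)
  dens_p <- as.numeric(acc_p) / (nfr * area * widths)
  dens_c <- as.numeric(acc_c) / (nfr * area * widths)
  zc <- Lz / 2
  core <- abs(centers - zc) <= half_width
  rho_h <- mean(dens_p[core])
  dmax <- max(dens_p)
  bl <- .band_crossings(centers, dens_p, dmax, zc, "left")
  br <- .band_crossings(centers, dens_p, dmax, zc, "right")
  band <- data.frame(side = c("left", "right"),
                     z_inner = unname(c(bl["inner"], br["inner"])),
                     z_outer = unname(c(bl["outer"], br["outer"])))
  structure(list(z = centers, protein = dens_p, crowder = dens_c,
                 rho_h = rho_h, surface_band = band, max_density = dmax,
                 bin_width = bin_width, half_width = half_width, Lz = Lz,
                 weight = weight, n_frames = nfr),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("z-density profile: %d bins of %g nm, %d frames\n",
              length(x$z), x$bin_width, x$n_frames))
  cat(sprintf("  rho_h = %.4g %s/nm^3\n", x$rho_h,
              if (x$weight == "mass") "amu" else "beads"))
  print(x$surface_band)
  invisible(x)
}

#' @method tidy density_profile
#' @export
tidy.density_profile <- function(x, ...) {
  tibble::tibble(z = rep(x$z, 2),
                 species = rep(c("protein", "crowder"), each = length(x$z)),
                 density = c(x$protein, x$crowder))
}

#' @method glance density_profile
#' @export
glance.density_profile <- function(x, ...) {
  tibble::tibble(rho_h = x$rho_h, max_density = x$max_density,
                 n_frames = x$n_frames, bin_width = x$bin_width)
}

#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$density,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$rho_h, linetype = "dashed") +
    ggplot2::labs(x = "z (nm)",
                  y = paste0("density (",
                             if (object$weight == "mass") "amu" else "beads",
                             "/nm^3)"))
}

# --- crowder RDF and classification ----------------------------------------

# protein centre of mass; circular mean per axis in periodic boxes
.protein_com <- function(frame, topology) {
  prot <- !topology$is_crowder
  pos <- frame$positions[prot, , drop = FALSE]
  m <- topology$mass[prot]
  if (topology$geometry$kind == "box") {
    L <- topology$geometry$L
    vapply(1:3, function(k) {
      th <- 2 * pi * pos[, k] / L[k]
      (L[k] / (2 * pi)) *
        atan2(sum(m * sin(th)), sum(m * cos(th))) %% (2 * pi)
    }, numeric(1))
  } else colSums(pos * m) / sum(m)
}

#' Radial density of crowders about the protein centre of mass
#'
#' Counts crowder beads in spherical shells of thickness `dr` centred on
#' the protein centre of mass, averaged over analysed frames, and
#' normalises by the shell volume `4 pi r^2 dr` evaluated at bin centres.
#'
#' @param traj A `cg_trajectory` containing at least one crowder.
#' @param dr Shell thickness, nm.
#' @param r_max Outermost shell radius, nm (default: half the smallest box
#'   edge, or the confinement radius).
#' @param t_init Equilibration discard, ps.
#' @return An `rdf` object with `r` (bin centres), `rho` (number density,
#'   1/nm^3) and `P` (mean shell counts).
#' @export
rdf_crowders <- function(traj, dr = 0.1, r_max = NULL, t_init = 0) {
  topo <- traj$topology
  nc <- sum(topo$is_crowder)
  frames <- .analysis_frames(traj, t_init)
  if (is.null(r_max))
    r_max <- if (topo$geometry$kind == "box") min(topo$geometry$L) / 2
             else topo$geometry$radius * 1.5
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  P <- numeric(nb)
  if (nc > 0) {
    for (f in frames) {
      com <- .protein_com(f, topo)
      d <- sweep(f$positions[topo$is_crowder, , drop = FALSE], 2, com)
      if (topo$geometry$kind == "box")
        for (k in 1:3) d[, k] <- .min_image(d[, k], topo$geometry$L[k])
      r <- sqrt(rowSums(d^2))
      r <- r[r < r_max]
      if (length(r)) {
        bin <- pmin(findInterval(r, edges, rightmost.closed = TRUE), nb)
        P <- P + tabulate(bin, nbins = nb)
      }
    }
    P <- P / length(frames)
  }
  structure(list(r = centers, P = P, rho = P / (4 * pi * centers^2 * dr),
                 dr = dr, n_frames = length(frames), n_crowders = nc),
            class = "rdf")
}

#' @method tidy rdf
#' @export
tidy.rdf <- function(x, ...) {
  tibble::tibble(r = x$r, rho = x$rho, P = x$P)
}

#' @method autoplot rdf
#' @export
autoplot.rdf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = "crowder density (1/nm^3)")
}

#' Classify crowders as internal or external to the protein
#'
#' A crowder is internal when it lies within the mean radius of gyration of
#' the protein centre of mass, and external when it lies in a proximity
#' shell of width `shell` just outside that radius. Fractions are averaged
#' over analysed frames.
#'
#' @param traj A `cg_trajectory`.
#' @param rg_mean Mean protein radius of gyration, nm.
#' @param shell Width of the external proximity shell, nm.
#' @param t_init Equilibration discard, ps.
#' @return Named numeric: `internal` and `external` fractions of the
#'   crowder population.
#' @export
classify_crowders <- function(traj, rg_mean, shell = 1.0, t_init = 0) {
  if (rg_mean <= 0) stop("rg_mean must be positive")
  topo <- traj$topology
  nc <- sum(topo$is_crowder)
  if (nc == 0) return(c(internal = 0, external = 0))
  frames <- .analysis_frames(traj, t_init)
  fr_int <- fr_ext <- numeric(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    com <- .protein_com(f, topo)
    d <- sweep(f$positions[topo$is_crowder, , drop = FALSE], 2, com)
    if (topo$geometry$kind == "box")
      for (j in 1:3) d[, j] <- .min_image(d[, j], topo$geometry$L[j])
    r <- sqrt(rowSums(d^2))
    fr_int[k] <- mean(r < rg_mean)
    fr_ext[k] <- mean(r >= rg_mean & r < rg_mean + shell)
  }
  c(internal = mean(fr_int), external = mean(fr_ext))
}

# --- MSD and diffusion ------------------------------------------------------

# unwrapped centre-of-mass z of one chain across a list of frames
.com_z_series <- function(frames, topology, chain) {
  idx <- chain_beads(topology, chain)
  m <- topology$mass[idx]
  z <- vapply(frames, function(f) {
    p <- .unwrap_chain(f$positions[idx, , drop = FALSE], topology$geometry)
    sum(p[, 3] * m) / sum(m)
  }, numeric(1))
  if (topology$geometry$kind == "box") {
    Lz <- topology$geometry$L[3]
    dz <- .min_image(diff(z), Lz)
    z <- cumsum(c(z[1], dz))
  }
  z
}

#' Mean-square displacement of chain centres of mass along z
#'
#' Time-averaged over all sliding origins,
#' `MSD(dt) = mean_t [z(t + dt) - z(t)]^2`, using the periodic-unwrapped
#' z-coordinate of each chain's centre of mass, then averaged over chains.
#'
#' @param traj A `cg_trajectory` with at least two frames.
#' @param max_lag Largest lag in frames (default: half the trajectory).
#' @param chains Chain indices (default all).
#' @param t_init Equilibration discard, ps.
#' @return An `msd_curve` object with `lag_time` (ps) and `msd` (nm^2),
#'   including the zero-lag point.
#' @export
msd <- function(traj, max_lag = NULL, chains = NULL, t_init = 0) {
  topo <- traj$topology
  frames <- .analysis_frames(traj, t_init)
  n <- length(frames)
  if (n < 2) stop("need at least two frames")
  if (is.null(max_lag)) max_lag <- n %/% 2
  if (max_lag >= n)
    stop("max_lag (", max_lag, " frames) must be below the trajectory ",
         "length (", n, " frames)")
  if (is.null(chains)) chains <- seq_len(topo$n_chains)
  times <- vapply(frames, `[[`, numeric(1), "time")
  dt <- mean(diff(times))
  acc <- numeric(max_lag)
  for (ch in chains) {
    z <- .com_z_series(frames, topo, ch)
    for (lag in seq_len(max_lag)) {
      d <- z[(1 + lag):n] - z[1:(n - lag)]
      acc[lag] <- acc[lag] + mean(d^2)
    }
  }
  structure(list(lag_time = c(0, seq_len(max_lag) * dt),
                 msd = c(0, acc / length(chains)),
                 dt = dt, n_frames = n, n_chains = length(chains)),
            class = "msd_curve")
}

#' @method tidy msd_curve
#' @export
tidy.msd_curve <- function(x, ...) {
  tibble::tibble(lag_time = x$lag_time, msd = x$msd)
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Least-squares straight line in log-log space,
#' `log MSD = alpha log(dt) + log(2 D)`: the slope is the diffusion
#' exponent alpha (1 for normal diffusion, below 1 for subdiffusion, 2 for
#' ballistic motion) and the intercept gives D.
#'
#' @param msd_curve An `msd_curve` (or data frame with `lag_time`, `msd`).
#' @param fit_range Length-2 lag-time interval (ps) used in the fit;
#'   default from the smallest positive lag to 10% of the largest.
#' @param log_spaced Subsample the fit window to approximately
#'   logarithmically spaced lags, so densely packed long lags (which are
#'   strongly correlated in time-averaged MSDs) do not dominate the
#'   least-squares line.
#' @param n_lags Number of log-spaced lags when `log_spaced = TRUE`.
#' @return An `msd_fit`: the curve plus `alpha`, `D` (nm^2/ps per the 1D
#'   convention `MSD = 2 D dt^alpha`), `fit_range` and fit residuals.
#' @export
fit_diffusion <- function(msd_curve, fit_range = NULL, log_spaced = FALSE,
                          n_lags = 25) {
  lt <- msd_curve$lag_time
  ms <- msd_curve$msd
  pos <- lt > 0
  if (is.null(fit_range))
    fit_range <- c(min(lt[pos]), max(lt[pos]) * 0.1)
  sel <- pos & lt >= fit_range[1] & lt <= fit_range[2]
  if (sum(sel) < 2) stop("fit_range selects fewer than two lags")
  if (log_spaced) {
    cand <- lt[sel]
    want <- 10^seq(log10(min(cand)), log10(max(cand)), length.out = n_lags)
    pick <- unique(vapply(want, function(w) cand[which.min(abs(cand - w))],
                          numeric(1)))
    sel <- sel & lt %in% pick
  }
  if (any(ms[sel] <= 0))
    stop("nonpositive MSD values inside the fit range")
  fit <- lm(log(ms[sel]) ~ log(lt[sel]))
  alpha <- unname(coef(fit)[2])
  D <- exp(unname(coef(fit)[1])) / 2
  structure(list(lag_time = lt, msd = ms, alpha = alpha, D = D,
                 fit_range = fit_range,
                 residuals = unname(stats::residuals(fit)),
                 dt = msd_curve$dt %||% NULL),
            class = "msd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD power-law fit: alpha = %.4f, D = %.4g nm^2/ps\n",
              x$alpha, x$D))
  invisible(x)
}

#' @method tidy msd_fit
#' @export
tidy.msd_fit <- function(x, ...) {
  tibble::tibble(lag_time = x$lag_time, msd = x$msd)
}

#' @method glance msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, D = x$D,
                 fit_lo = x$fit_range[1], fit_hi = x$fit_range[2],
                 rms_residual = sqrt(mean(x$residuals^2)))
}

#' @method autoplot msd_fit
#' @export
autoplot.msd_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$lag_time > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_time, y = .data$msd)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_line(
      data = data.frame(lag_time = df$lag_time,
                        msd = 2 * object$D * df$lag_time^object$alpha),
      colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (ps)", y = "MSD (nm^2)")
}

# --- contact maps -----------------------------------------------------------

.contact_cutoffs <- function(topology, chain_len, cutoff_factor = 0.75) {
  sg <- topology$sigma[chain_beads(topology, 1)]
  cutoff_factor * outer(sg, sg, "+")
}

.pair_dist2 <- function(pa, pb, geometry) {
  d2 <- matrix(0, nrow(pa), nrow(pb))
  for (k in 1:3) {
    d <- outer(pa[, k], pb[, k], "-")
    if (geometry$kind == "box") d <- .min_image(d, geometry$L[k])
    d2 <- d2 + d^2
  }
  d2
}

#' Time-averaged residue-residue contact map
#'
#' Two residues are in contact when their distance is below
#' `cutoff_factor * (sigma_i + sigma_j)` (default factor 0.75). The
#' indicator is time-averaged over analysed frames; intra-chain maps
#' average over chains and exclude near-diagonal pairs
#' (`|i - j| < min_seq_sep`), inter-chain maps average over all ordered
#' chain pairs. All chains must have equal length.
#'
#' @param traj A `cg_trajectory`.
#' @param flavor `"intra"` or `"inter"`.
#' @param min_seq_sep Smallest `|i - j|` retained in intra maps.
#' @param cutoff_factor Contact cutoff as a multiple of `sigma_i + sigma_j`.
#' @param t_init Equilibration discard, ps.
#' @return A `contact_map`: `matrix` (L x L, entries in `[0, 1]`),
#'   `flavor`, `n_frames` and the number of chain (pairs) averaged over.
#' @export
contact_map <- function(traj, flavor = c("intra", "inter"),
                        min_seq_sep = 3, cutoff_factor = 0.75, t_init = 0) {
  flavor <- match.arg(flavor)
  topo <- traj$topology
  lens <- topo$chain_lengths
  if (!length(lens)) stop("no chains in topology")
  if (length(unique(lens)) != 1)
    stop("contact maps require equal-length chains")
  if (flavor == "inter" && topo$n_chains < 2)
    stop("inter-chain contact map needs at least two chains")
  L <- lens[1]
  frames <- .analysis_frames(traj, t_init)
  cut2 <- .contact_cutoffs(topo, L, cutoff_factor)^2
  acc <- matrix(0, L, L)
  n_avg <- 0L
  geometry <- topo$geometry
  idx <- lapply(seq_len(topo$n_chains), chain_beads, topology = topo)
  if (flavor == "intra") {
    keep <- abs(outer(seq_len(L), seq_len(L), "-")) >= min_seq_sep
    for (f in frames) for (a in seq_len(topo$n_chains)) {
      p <- f$positions[idx[[a]], , drop = FALSE]
      acc <- acc + (( .pair_dist2(p, p, geometry) < cut2) & keep)
      n_avg <- n_avg + 1L
    }
  } else {
    pairs <- which(outer(seq_len(topo$n_chains), seq_len(topo$n_chains),
                         "!="), arr.ind = TRUE)
    for (f in frames) for (r in seq_len(nrow(pairs))) {
      pa <- f$positions[idx[[pairs[r, 1]]], , drop = FALSE]
      pb <- f$positions[idx[[pairs[r, 2]]], , drop = FALSE]
      acc <- acc + (.pair_dist2(pa, pb, geometry) < cut2)
      n_avg <- n_avg + 1L
    }
  }
  structure(list(matrix = acc / n_avg, flavor = flavor,
                 n_frames = length(frames),
                 n_averaged = n_avg / length(frames),
                 min_seq_sep = if (flavor == "intra") min_seq_sep else NA,
                 cutoff_factor = cutoff_factor),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("%s-chain contact map, %d x %d, %d frames, mean N_c = %.4g\n",
              x$flavor, nrow(x$matrix), ncol(x$matrix), x$n_frames,
              mean(x$matrix)))
  invisible(x)
}

#' @method tidy contact_map
#' @export
tidy.contact_map <- function(x, ...) {
  L <- nrow(x$matrix)
  tibble::tibble(i = rep(seq_len(L), times = L),
                 j = rep(seq_len(L), each = L),
                 contact = as.vector(x$matrix))
}

#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$i, y = .data$j,
                               fill = .data$contact)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue i", y = "residue j",
                  fill = expression(N[c]))
}

#' Region-block average of a contact map
#'
#' Mean of the inter-chain contact matrix over the block of residue pairs
#' `I x J`, i.e. the block sum divided by `length(I) * length(J)`. The two
#' regions may coincide (e.g. Helix-Helix).
#'
#' @param cmap A [contact_map()] or a bare contact matrix.
#' @param region_I,region_J [region_spec()] objects (local ranges are used)
#'   or integer index vectors.
#' @return The region contact number (scalar).
#' @export
region_contact_number <- function(cmap, region_I, region_J) {
  M <- if (inherits(cmap, "contact_map")) cmap$matrix else cmap
  ri <- .region_idx(region_I, nrow(M))
  rj <- .region_idx(region_J, ncol(M))
  mean(M[ri, rj, drop = FALSE])
}

.region_idx <- function(region, n) {
  idx <- if (inherits(region, "region_spec"))
    region$local_range[1]:region$local_range[2] else as.integer(region)
  if (!length(idx)) stop("empty region")
  if (any(idx < 1 | idx > n)) stop("region indices outside the chain")
  idx
}

#' Per-frame region contact series
#'
#' For each analysed frame and each ordered chain pair, computes the
#' inter-chain region contact number between regions I and J (single-frame
#' indicator matrices block-averaged as in [region_contact_number()]).
#'
#' @param traj A `cg_trajectory` with at least two chains.
#' @param region_I,region_J Regions ([region_spec()] or index vectors).
#' @param cutoff_factor Contact cutoff factor.
#' @param t_init Equilibration discard, ps.
#' @return A `region_contact_series`: `values` (frames x chain-pairs
#'   matrix), `time` (ps), `dt` and the region pair.
#' @export
region_contact_series <- function(traj, region_I, region_J,
                                  cutoff_factor = 0.75, t_init = 0) {
  topo <- traj$topology
  if (topo$n_chains < 2) stop("need at least two chains")
  frames <- .analysis_frames(traj, t_init)
  L <- topo$chain_lengths[1]
  ri <- .region_idx(region_I, L)
  rj <- .region_idx(region_J, L)
  cut2 <- .contact_cutoffs(topo, L, cutoff_factor)[ri, rj, drop = FALSE]^2
  idx <- lapply(seq_len(topo$n_chains), chain_beads, topology = topo)
  pairs <- which(outer(seq_len(topo$n_chains), seq_len(topo$n_chains),
                       "!="), arr.ind = TRUE)
  vals <- matrix(0, length(frames), nrow(pairs))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    for (r in seq_len(nrow(pairs))) {
      pa <- f$positions[idx[[pairs[r, 1]]][ri], , drop = FALSE]
      pb <- f$positions[idx[[pairs[r, 2]]][rj], , drop = FALSE]
      vals[k, r] <- mean(.pair_dist2(pa, pb, topo$geometry) < cut2)
    }
  }
  structure(list(values = vals, time = vapply(frames, `[[`, numeric(1),
                                              "time"),
                 dt = mean(diff(vapply(frames, `[[`, numeric(1), "time"))),
                 region_I = region_I, region_J = region_J),
            class = "region_contact_series")
}

#' Contact autocorrelation and relaxation time
#'
#' Mean-subtracted, variance-normalised time autocorrelation of a contact
#' series (`L(0) = 1`), averaged across series (chain pairs) when several
#' are given, followed by a least-squares exponential fit
#' `L(dt) = exp(-dt / tau)` of `log L` over the lags where the ACF exceeds
#' `fit_floor`.
#'
#' @param series A [region_contact_series()], a numeric vector, or a matrix
#'   with one series per column.
#' @param dt Frame spacing, ps (taken from the series object if present).
#' @param max_lag Largest lag in frames (default half the series).
#' @param fit_floor Positive ACF floor delimiting the fit window.
#' @return A `contact_acf`: `lag_time`, `acf`, and `tau` (ps).
#' @export
contact_acf_tau <- function(series, dt = NULL, max_lag = NULL,
                            fit_floor = 0.05) {
  if (inherits(series, "region_contact_series")) {
    if (is.null(dt)) dt <- series$dt
    vals <- series$values
  } else vals <- as.matrix(series)
  if (is.null(dt)) dt <- 1
  n <- nrow(vals)
  if (is.null(max_lag)) max_lag <- max(1L, n %/% 2L)
  keep <- apply(vals, 2, var) > 0
  if (!any(keep)) stop("degenerate contact series: zero variance")
  acfs <- vapply(which(keep), function(k)
    as.vector(acf(vals[, k], lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf), numeric(max_lag + 1L))
  a <- rowMeans(acfs)
  lag_time <- (0:max_lag) * dt
  above <- a > fit_floor
  # contiguous window from lag zero
  win <- if (all(above)) seq_along(a) else seq_len(which.min(above) - 1L)
  if (length(win) >= 2) {
    fit <- lm(log(a[win]) ~ lag_time[win])
    tau <- -1 / unname(coef(fit)[2])
  } else if (a[2] > 0) {
    # correlations die within one frame: read tau off the first lag
    tau <- -dt / log(a[2])
  } else if (all(a[-1] <= 0)) {
    stop("ACF is non-positive at every lag; no exponential fit possible")
  } else {
    tau <- 0
  }
  structure(list(lag_time = lag_time, acf = a, tau = tau,
                 fit_floor = fit_floor, n_series = sum(keep)),
            class = "contact_acf")
}

#' @export
print.contact_acf <- function(x, ...) {
  cat(sprintf("contact ACF: tau = %.4g ps (%d series averaged)\n",
              x$tau, x$n_series))
  invisible(x)
}

#' @method tidy contact_acf
#' @export
tidy.contact_acf <- function(x, ...) {
  tibble::tibble(lag_time = x$lag_time, acf = x$acf)
}

#' @method autoplot contact_acf
#' @export
autoplot.contact_acf <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$lag_time, y = .data$acf)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_line(
      data = data.frame(lag_time = object$lag_time,
                        acf = exp(-object$lag_time / object$tau)),
      colour = "red") +
    ggplot2::labs(x = "lag time (ps)", y = "L(lag)")
}

# --- segment orientation ----------------------------------------------------

#' Orientation of one chain segment relative to z
#'
#' Draws a representative intramolecular vector from the segment by random
#' residue selection: for Helix- and IDR1-type segments the base point
#' comes from the second half and the tip from the first half; for
#' IDR2-type segments the base comes from the first half and the tip from
#' the second half (`sense = "reverse"` vs `"forward"`). The orientation
#' angle is `phi = acos(r . z / |r|)` in degrees.
#'
#' @param frame A trajectory frame or positions matrix.
#' @param topology A `cg_topology`.
#' @param chain Chain index.
#' @param region A [region_spec()] or local index vector (length >= 2).
#' @param sense `"auto"` (reverse for regions named IDR2, forward
#'   otherwise), `"forward"` (base first half) or `"reverse"` (base second
#'   half).
#' @param max_retries Resampling attempts when the two residues coincide.
#' @return List with `phi` (degrees), `z_com` (nm) and the drawn indices.
#' @export
segment_orientation <- function(frame, topology, chain, region,
                                sense = c("auto", "forward", "reverse"),
                                max_retries = 10) {
  sense <- match.arg(sense)
  pos <- if (is.list(frame)) frame$positions else frame
  idx <- chain_beads(topology, chain)
  L <- length(idx)
  ri <- .region_idx(region, L)
  if (length(ri) < 2) stop("region must contain at least two residues")
  if (sense == "auto")
    sense <- if (inherits(region, "region_spec") && region$name == "IDR2")
      "forward" else "reverse"
  # unwrap the chain so segment vectors are not broken across the boundary
  p <- .unwrap_chain(pos[idx, , drop = FALSE], topology$geometry)
  nloc <- length(ri)
  first_half <- ri[seq_len(nloc %/% 2)]
  second_half <- ri[(nloc %/% 2 + 1):nloc]
  for (a in seq_len(max_retries)) {
    if (sense == "reverse") {
      i0 <- if (length(second_half) == 1) second_half
            else sample(second_half, 1)
      i1 <- if (length(first_half) == 1) first_half
            else sample(first_half, 1)
    } else {
      i0 <- if (length(first_half) == 1) first_half
            else sample(first_half, 1)
      i1 <- if (length(second_half) == 1) second_half
            else sample(second_half, 1)
    }
    v <- p[i1, ] - p[i0, ]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) {
      m <- topology$mass[idx][ri]
      z_com <- sum(p[ri, 3] * m) / sum(m)
      return(list(phi = acos(max(-1, min(1, v[3] / nv))) * 180 / pi,
                  z_com = z_com, i0 = i0, i1 = i1))
    }
  }
  stop("coincident residues: zero-length orientation vector after ",
       max_retries, " retries")
}

#' Orientation-versus-z map of chain segments
#'
#' Samples segment orientations for every analysed frame, chain and region
#' (with the same per-frame recentring as [density_profile()]), builds the
#' 2D histogram of phi versus z, and extracts the surface-restricted phi
#' distributions for the left and right interfaces separately using the
#' profile's 0.2-0.8 density band.
#'
#' @param traj A `cg_trajectory` in slab geometry.
#' @param regions Named list of [region_spec()] (default from the
#'   topology).
#' @param profile A [density_profile()] (computed when omitted).
#' @param n_samples Orientation draws per frame, chain and region.
#' @param phi_bin,z_bin Histogram bin widths (degrees, nm).
#' @param t_init Equilibration discard, ps.
#' @return An `orientation_map`: `samples` (data frame with `region`,
#'   `phi`, `z`, `side`), histogram `counts` with `phi_breaks`/`z_breaks`,
#'   and the profile used.
#' @export
orientation_map <- function(traj, regions = NULL, profile = NULL,
                            n_samples = 1, phi_bin = 10, z_bin = NULL,
                            t_init = 0) {
  topo <- traj$topology
  if (is.null(regions)) regions <- topo$regions
  if (is.null(regions)) stop("no regions defined")
  if (is.null(profile))
    profile <- density_profile(traj, t_init = t_init)
  if (is.null(z_bin)) z_bin <- profile$bin_width
  band <- profile$surface_band
  if (anyNA(band$z_inner) || anyNA(band$z_outer))
    stop("interface detection failed: no 0.2-0.8 density band found")
  frames <- .analysis_frames(traj, t_init)
  Lz <- topo$geometry$L[3]
  prot <- !topo$is_crowder
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    shift <- .recenter_shift(f$positions[prot, 3], topo$mass[prot], Lz)
    out <- list()
    for (rn in names(regions)) for (ch in seq_len(topo$n_chains))
      for (s in seq_len(n_samples)) {
        o <- segment_orientation(f, topo, ch, regions[[rn]])
        z <- (o$z_com + shift) %% Lz
        out[[length(out) + 1L]] <-
          data.frame(region = rn, phi = o$phi, z = z)
      }
    rows[[k]] <- do.call(rbind, out)
  }
  samples <- do.call(rbind, rows)
  lb <- band[band$side == "left", ]
  rb <- band[band$side == "right", ]
  samples$side <- "interior"
  samples$side[samples$z >= lb$z_outer & samples$z <= lb$z_inner] <- "left"
  samples$side[samples$z <= rb$z_outer & samples$z >= rb$z_inner] <- "right"
  phi_breaks <- seq(0, 180, by = phi_bin)
  z_breaks <- seq(0, Lz, by = z_bin)
  if (tail(z_breaks, 1) < Lz) z_breaks <- c(z_breaks, Lz)
  counts <- table(
    phi = cut(samples$phi, phi_breaks, include.lowest = TRUE),
    z = cut(samples$z, z_breaks, include.lowest = TRUE),
    region = samples$region)
  structure(list(samples = samples, counts = counts,
                 phi_breaks = phi_breaks, z_breaks = z_breaks,
                 profile = profile, n_samples = n_samples),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("orientation map: %d samples, regions %s\n",
              nrow(x$samples),
              paste(unique(x$samples$region), collapse = ", ")))
  print(table(x$samples$side))
  invisible(x)
}

#' @method tidy orientation_map
#' @export
tidy.orientation_map <- function(x, ...) {
  tibble::as_tibble(x$samples)
}

#' @method autoplot orientation_map
#' @export
autoplot.orientation_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$z, y = .data$phi)) +
    ggplot2::geom_bin2d(binwidth = c(diff(object$z_breaks)[1],
                                     diff(object$phi_breaks)[1])) +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "z (nm)", y = expression(phi ~ "(degrees)"))
}

#' @importFrom ggplot2 .data
NULL
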