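test_that("radius of gyration matches hand-computed cases", {
  tab <- one_bead_table(mass = 100)
  topo <- build_topology("GGG", tab, geometry_box(100, 100, 100))
  coincident <- matrix(50, 3, 3)
  expect_equal(radius_of_gyration(coincident, topo), 0)
  # three equal masses collinear at 0, 1, 2 nm: Rg = sqrt(2/3)
  collinear <- cbind(c(50, 51, 52), 50, 50)
  expect_equal(radius_of_gyration(collinear, topo), sqrt(2 / 3))
  # two equal masses at distance d: Rg = d / 2
  topo2 <- build_topology("GG", tab, geometry_box(100, 100, 100))
  expect_equal(radius_of_gyration(cbind(c(50, 53), 50, 50), topo2), 1.5)
  # unwrapping: a bond crossing the boundary is not stretched
  wrapped <- cbind(c(0.1, 99.9, 99.5), 50, 50)
  expect_lt(radius_of_gyration(wrapped, topo), 1)
})

test_that("density profile recovers a tanh slab's plateau and interface", {
  fx <- gen_tanh_slab(plateau = 40, width = 1, box = geometry_box(10, 10, 50),
                      n_beads = 1e5, seed = 3)
  pr <- density_profile(fx$trajectory, bin_width = 0.5, weight = "count",
                        half_width = 5)
  expect_equal(pr$rho_h, fx$key$rho_h, tolerance = 0.02)
  # surface band endpoints at the analytic inverse-tanh crossings (one bin)
  zc <- 25
  expect_equal(zc - pr$surface_band$z_inner[1], fx$key$d_inner,
               tolerance = 0.5 / fx$key$d_inner)
  expect_equal(zc - pr$surface_band$z_outer[1], fx$key$d_outer,
               tolerance = 0.5 / fx$key$d_outer)
  expect_equal(pr$surface_band$z_inner[2] - zc, fx$key$d_inner,
               tolerance = 0.5 / fx$key$d_inner)
  # profile is symmetric about the centre within noise
  half <- length(pr$z) %/% 2
  expect_equal(pr$protein[1:half], rev(pr$protein)[1:half],
               tolerance = 0.15)
})

test_that("density profile handles uniform and degenerate inputs", {
  # uniform ideal gas: flat profile, rho_h equals the bulk density
  ig <- gen_ideal_gas(5e4, geometry_box(10, 10, 20), seed = 5)
  pr <- density_profile(ig$trajectory, bin_width = 1, weight = "count",
                        recenter = FALSE)
  expect_equal(pr$rho_h, ig$key$density, tolerance = 0.02)
  expect_lt(max(abs(pr$protein - ig$key$density)) / ig$key$density, 0.1)
  # all beads in one thin sheet: single occupied bin, counts conserved
  tab <- one_bead_table()
  topo <- build_topology(rep("G", 200), tab, geometry_box(5, 5, 20))
  pos <- cbind(runif(200, 0, 5), runif(200, 0, 5), 7.3)
  traj <- new_trajectory(list(list(time = 0, positions = pos,
                                   box = topo$geometry)), topo)
  pr2 <- density_profile(traj, bin_width = 1, weight = "count",
                         recenter = FALSE)
  expect_equal(sum(pr2$protein * 1 * 25), 200)
  expect_equal(sum(pr2$protein > 0), 1L)
})

test_that("equilibration discard only selects frames, never the estimator", {
  fx <- gen_tanh_slab(plateau = 40, width = 1, box = geometry_box(8, 8, 40),
                      n_beads = 2e4, seed = 9, n_frames = 6)
  pr_all <- density_profile(fx$trajectory, bin_width = 1, weight = "count")
  pr_cut <- density_profile(fx$trajectory, bin_width = 1, weight = "count",
                            t_init = 3)
  expect_equal(pr_cut$n_frames, 3L)
  # recomputing from the kept frames alone gives the identical object
  traj_cut <- new_trajectory(fx$trajectory$frames[4:6],
                             fx$trajectory$topology)
  pr_manual <- density_profile(traj_cut, bin_width = 1, weight = "count")
  expect_equal(pr_cut$protein, pr_manual$protein)
  expect_equal(pr_cut$rho_h, pr_manual$rho_h)
})

test_that("crowder RDF normalises shells correctly", {
  # one crowder frozen at distance d: all mass in that bin, 1/(4 pi d^2 dr)
  tab <- one_bead_table()
  geom <- geometry_box(30, 30, 30)
  topo <- build_topology("G", tab, geom, crowder_mode = "repulsive",
                         crowder_fraction = 1e-9)
  topo$n_beads <- 2L
  topo$chain <- c(1L, NA); topo$local_index <- c(1L, NA)
  topo$code <- c("G", NA)
  topo$mass <- c(100, 1500); topo$sigma <- c(0.45, 1.6)
  topo$lambda0 <- c(0.5, 0); topo$charge <- c(0L, 0L)
  topo$is_crowder <- c(FALSE, TRUE)
  topo$crowder <- crowder_spec("repulsive")
  pos <- rbind(c(15, 15, 15), c(15 + 4.23, 15, 15))
  traj <- new_trajectory(list(list(time = 0, positions = pos, box = geom)),
                         topo)
  rr <- rdf_crowders(traj, dr = 0.1)
  k <- which(rr$P > 0)
  expect_length(k, 1L)
  expect_true(4.23 >= k * 0.1 - 0.1 && 4.23 <= k * 0.1)
  expect_equal(rr$rho[k], 1 / (4 * pi * rr$r[k]^2 * 0.1))

  # uniform random crowders: flat at bulk density beyond the core
  ig <- gen_ideal_gas(3000, geometry_box(20, 20, 20), seed = 5,
                      n_frames = 30, as_crowders = TRUE)
  rr2 <- rdf_crowders(ig$trajectory, dr = 0.5)
  sel <- rr2$r > 3 & rr2$r < 9
  expect_lt(max(abs(rr2$rho[sel] - ig$key$density)) / ig$key$density, 0.05)

  # no crowders: all-zero profile, guarded
  topo0 <- build_topology("GG", tab, geom)
  traj0 <- new_trajectory(list(list(time = 0,
                                    positions = rbind(c(15, 15, 15),
                                                      c(15.4, 15, 15)),
                                    box = geom)), topo0)
  rr0 <- rdf_crowders(traj0, dr = 0.5)
  expect_true(all(rr0$rho == 0))
})

test_that("crowders classify as internal or external by construction", {
  tab <- one_bead_table()
  geom <- geometry_box(40, 40, 40)
  fx <- gen_ideal_gas(10, geom, seed = 2, as_crowders = TRUE)
  topo <- fx$trajectory$topology
  # place 3 inside rg, 2 in the shell, 5 far outside
  center <- c(20, 20, 20)
  rg <- 3; shell <- 1
  offs <- c(0.5, 1.0, 2.0, 3.3, 3.8, 8, 9, 10, 11, 12)
  pos <- rbind(center,
               t(vapply(offs, function(d) center + c(d, 0, 0), numeric(3))))
  traj <- new_trajectory(list(list(time = 0, positions = pos, box = geom)),
                         topo)
  fr <- classify_crowders(traj, rg_mean = rg, shell = shell)
  expect_equal(unname(fr["internal"]), 0.3)
  expect_equal(unname(fr["external"]), 0.2)
  # all far beyond both thresholds: nothing classified
  pos2 <- rbind(center, matrix(rep(center + c(15, 0, 0), 10), ncol = 3,
                               byrow = TRUE) + cbind(seq(0, 4.5, 0.5), 0, 0))
  traj2 <- new_trajectory(list(list(time = 0, positions = pos2,
                                    box = geom)), topo)
  fr2 <- classify_crowders(traj2, rg_mean = rg, shell = shell)
  expect_equal(unname(fr2), c(0, 0))
})

test_that("MSD reproduces static, ballistic and Brownian motion", {
  tab <- one_bead_table()
  geom <- geometry_box(1e4, 1e4, 1e4)
  topo <- build_topology("G", tab, geom)
  mk_traj <- function(z) new_trajectory(lapply(seq_along(z), function(k)
    list(time = k - 1, positions = matrix(c(5e3, 5e3, z[k]), 1),
         box = geom)), topo)
  # static
  m0 <- msd(mk_traj(rep(7, 50)), max_lag = 10)
  expect_true(all(m0$msd == 0))
  # ballistic z = v t: MSD = v^2 dt^2, alpha = 2 exactly
  v <- 0.3
  mb <- msd(mk_traj(5e3 + v * (0:199)), max_lag = 50)
  expect_equal(mb$msd, c(0, v^2 * (1:50)^2), tolerance = 1e-10)
  fb <- fit_diffusion(mb, fit_range = c(1, 20))
  expect_equal(fb$alpha, 2, tolerance = 1e-8)
  # Brownian fixture: MSD(dt) ~ 2 D dt
  fx <- gen_brownian(D = 0.5, n_frames = 5000, dt = 1, seed = 7,
                     n_particles = 8)
  mm <- msd(fx$trajectory, max_lag = 100)
  expect_equal(mm$msd[11] / (2 * 0.5 * 10), 1, tolerance = 0.15)
  expect_error(msd(fx$trajectory, max_lag = 6000), "max_lag")
})

test_that("diffusion fit recovers exact power-law inputs", {
  exact <- list(lag_time = 0:100, msd = c(0, 2 * 0.5 * (1:100)))
  ft <- fit_diffusion(exact, fit_range = c(1, 100))
  expect_equal(ft$alpha, 1, tolerance = 1e-10)
  expect_equal(ft$D, 0.5, tolerance = 1e-10)
  ball <- list(lag_time = 0:100, msd = c(0, 0.04 * (1:100)^2))
  fb <- fit_diffusion(ball, fit_range = c(1, 100))
  expect_equal(fb$alpha, 2, tolerance = 1e-10)
  expect_error(fit_diffusion(list(lag_time = 0:10, msd = rep(0, 11)),
                             fit_range = c(1, 10)), "nonpositive")
})

test_that("contact maps count scheduled contacts exactly", {
  # symmetric schedule: entry equals the schedule mean
  sch <- c(rep(TRUE, 3), rep(FALSE, 7))
  ct <- gen_contact_toy(n_frames = 10, chain_len = 6,
                        pattern = list(list(i = 2, j = 3, schedule = sch),
                                       list(i = 3, j = 2, schedule = sch),
                                       list(i = 5, j = 5,
                                            schedule = rep(TRUE, 10))))
  cm <- contact_map(ct$trajectory, "inter")
  expect_equal(cm$matrix, ct$key$contact_map)
  expect_equal(cm$matrix[2, 3], 0.3)
  expect_equal(cm$matrix[5, 5], 1.0)
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 1))
  expect_equal(cm$matrix, t(cm$matrix))
  # always-out pair contributes zero
  expect_equal(cm$matrix[1, 1], 0)
})

test_that("contact maps equal the brute-force oracle on random systems", {
  tab <- one_bead_table(sigma = 0.5)
  geom <- geometry_box(4, 4, 4)
  topo <- build_topology(rep(strrep("G", 12), 3), tab, geom)
  sg <- rep(0.5, 12)
  for (s in 1:5) {
    set.seed(s)
    frames <- lapply(1:3, function(k)
      list(time = k - 1, positions = matrix(runif(108, 0, 4), ncol = 3),
           box = geom))
    traj <- new_trajectory(frames, topo)
    cm <- contact_map(traj, "inter")
    ref <- matrix(0, 12, 12)
    npairs <- 0
    for (f in frames) for (a in 1:3) for (b in 1:3) {
      if (a == b) next
      pa <- f$positions[(a - 1) * 12 + 1:12, ]
      pb <- f$positions[(b - 1) * 12 + 1:12, ]
      ref <- ref + brute_force_contacts(pa, pb, sg, sg, geom)
      npairs <- npairs + 1
    }
    expect_equal(cm$matrix, ref / npairs)
    # intra flavour on a single frozen frame equals the direct indicator
    traj1 <- new_trajectory(frames[1], topo)
    ci <- contact_map(traj1, "intra", min_seq_sep = 3)
    pa <- frames[[1]]$positions[1:12, ]
    ref_i <- matrix(0, 12, 12)
    for (a in 1:3) {
      pa <- frames[[1]]$positions[(a - 1) * 12 + 1:12, ]
      ref_i <- ref_i + brute_force_contacts(pa, pa, sg, sg, geom)
    }
    ref_i <- ref_i / 3
    ref_i[abs(outer(1:12, 1:12, "-")) < 3] <- 0
    expect_equal(ci$matrix, ref_i)
  }
})

test_that("region contact numbers are block means of the contact matrix", {
  M <- matrix(0, 10, 10)
  expect_equal(region_contact_number(M, 1:4, 5:10), 0)
  expect_equal(region_contact_number(matrix(1, 10, 10), 1:4, 5:10), 1)
  set.seed(13)
  Mr <- matrix(runif(100), 10, 10)
  # hand-summed block mean, same-region blocks included
  expect_equal(region_contact_number(Mr, 2:4, 6:9),
               sum(Mr[2:4, 6:9]) / (3 * 4))
  expect_equal(region_contact_number(Mr, 3:5, 3:5),
               sum(Mr[3:5, 3:5]) / 9)
  expect_error(region_contact_number(Mr, integer(0), 1:3), "empty region")
  expect_error(region_contact_number(Mr, 1:3, 9:12), "outside")
})

test_that("contact relaxation times come out of the ACF fit", {
  # exact exponential ACF input: tau recovered exactly
  lag <- 0:50
  series_like <- exp(-lag / 5)
  # build a synthetic series whose sample ACF is not exact; instead test
  # the fit path directly through an OU fixture and through the pure curve
  fit <- lm(log(series_like[1:20]) ~ lag[1:20])
  expect_equal(-1 / coef(fit)[2], 5, ignore_attr = TRUE, tolerance = 1e-10)

  # OU fixture: tau recovered within 20% at n = 1e5
  ou <- gen_ou_series(tau = 20, mean = 5, sd = 2, n = 1e5, dt = 1, seed = 9)
  ca <- contact_acf_tau(ou$series, dt = ou$dt, max_lag = 150)
  expect_equal(ca$acf[1], 1)
  expect_equal(ca$tau, 20, tolerance = 0.2)
  # lag-1 sample autocorrelation close to the exact discretisation value
  expect_equal(ca$acf[2], exp(-1 / 20), tolerance = 0.02)

  # white noise: tau below one frame interval
  set.seed(4)
  wn <- contact_acf_tau(rnorm(5e4), dt = 1, max_lag = 50)
  expect_lt(wn$tau, 1)

  expect_error(contact_acf_tau(rep(2, 100), dt = 1), "zero variance")
})

test_that("region contact series feed the ACF machinery end to end", {
  # alternating contact schedule between two chains
  sch <- rep(c(TRUE, TRUE, FALSE, FALSE), 10)
  ct <- gen_contact_toy(n_frames = 40, chain_len = 6,
                        pattern = list(list(i = 2, j = 2, schedule = sch)))
  rs <- region_contact_series(ct$trajectory, 1:3, 1:3)
  expect_equal(dim(rs$values), c(40L, 2L))
  # the scheduled pair lies in the 1:3 block: per-frame value is
  # schedule / (3 * 3) for the (1,2) ordering, transpose for (2,1)
  expect_equal(rs$values[, 1], as.numeric(sch) / 9)
  ca <- contact_acf_tau(rs)
  expect_equal(ca$acf[1], 1)
})

test_that("segment orientation angles follow the geometry", {
  fan <- gen_helix_fan(angles = c(0, 45, 90, 135, 180), z_positions = 25,
                       chain_len = 12, box = geometry_box(50, 50, 50))
  topo <- fan$trajectory$topology
  frame <- fan$trajectory$frames[[1]]
  set.seed(1)
  for (k in 1:5) {
    o <- segment_orientation(frame, topo, k, 1:12)
    expect_equal(o$phi, fan$key$phi[k], tolerance = 1e-9)
    expect_equal(o$z_com, 25, tolerance = 1e-9)
  }
  # coincident residues exhaust retries
  topo1 <- build_topology("GGGG", one_bead_table(), geometry_box(10, 10))
  frame1 <- list(time = 0, positions = matrix(5, 4, 3), box = NULL)
  expect_error(segment_orientation(frame1, topo1, 1, 1:4), "coincident")
})

test_that("isotropic orientation vectors give a sin(phi) histogram", {
  set.seed(17)
  n <- 1e5
  u <- matrix(rnorm(3 * n), ncol = 3)
  phi <- acos(u[, 3] / sqrt(rowSums(u^2))) * 180 / pi
  breaks <- seq(0, 180, by = 10)
  obs <- as.vector(table(cut(phi, breaks)))
  p <- diff(-cos(breaks * pi / 180)) / 2
  cs <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(cs$p.value, 0.001)
  # and the same through the fixture + segment_orientation path at n small
  fan <- gen_helix_fan(angles = runif(200, 0, 180), z_positions = 25,
                       chain_len = 8, box = geometry_box(100, 100, 50))
  set.seed(2)
  phis <- vapply(1:200, function(k)
    segment_orientation(fan$trajectory$frames[[1]],
                        fan$trajectory$topology, k, 1:8)$phi, numeric(1))
  expect_equal(phis, fan$key$phi, tolerance = 1e-9)
})

test_that("orientation maps localise mass and mirror across interfaces", {
  # all segments along z at the slab centre: histogram mass at phi ~ 0
  box <- geometry_box(20, 20, 50)
  fan <- gen_helix_fan(angles = rep(0, 30), z_positions = 25,
                       chain_len = 8, box = box, seed = 3)
  # a synthetic profile is needed: build a dense-centre trajectory by
  # reusing the tanh fixture's profile
  fx <- gen_tanh_slab(plateau = 30, width = 1.5, box = box, n_beads = 3e4,
                      seed = 5)
  pr <- density_profile(fx$trajectory, bin_width = 1, weight = "count",
                        half_width = 5)
  set.seed(6)
  om <- orientation_map(fan$trajectory, regions = list(seg = 1:8),
                        profile = pr, n_samples = 1)
  expect_true(all(om$samples$phi < 1e-6))
  expect_true(all(om$samples$side == "interior"))

  # mirror fixture: +z vectors at the left interface, -z at the right
  zl <- mean(unlist(pr$surface_band[1, c("z_inner", "z_outer")]))
  zr <- mean(unlist(pr$surface_band[2, c("z_inner", "z_outer")]))
  fan2 <- gen_helix_fan(angles = c(rep(0, 10), rep(180, 10)),
                        z_positions = c(rep(zl, 10), rep(zr, 10)),
                        chain_len = 8, box = box, seed = 4)
  # disable recentring effects by keeping the fan trajectory as the
  # protein: recentring shifts are small because chains are symmetric
  set.seed(7)
  om2 <- orientation_map(fan2$trajectory, regions = list(seg = 1:8),
                         profile = pr, n_samples = 1)
  left <- om2$samples$phi[om2$samples$side == "left"]
  right <- om2$samples$phi[om2$samples$side == "right"]
  if (length(left) && length(right)) {
    # mirror-symmetric about 90 degrees
    expect_equal(sort(left), sort(180 - right), tolerance = 1e-6)
  }
  expect_error(orientation_map(fan2$trajectory,
                               regions = list(seg = 1:8),
                               profile = local({
                                 p <- pr
                                 p$surface_band$z_inner <- NA_real_
                                 p
                               })), "interface")
})
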