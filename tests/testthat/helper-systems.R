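# Shared fixtures: small synthetic parameter tables (so no test depends on
# literature values) and a brute-force energy oracle kept deliberately
# independent of the package's vectorised kernels.

toy_table <- function(...) {
  hps_table(data.frame(
    code = c("A", "B", "E", "K"),
    mass = c(100, 120, 129, 128),
    sigma = c(0.50, 0.62, 0.592, 0.636),
    lambda0 = c(0.70, 0.30, 0.00, 0.40),
    charge = c(0L, 0L, -1L, 1L)), ...)
}

one_bead_table <- function(mass = 100, sigma = 0.45, lambda0 = 0.5) {
  hps_table(data.frame(code = "G", mass = mass, sigma = sigma,
                       lambda0 = lambda0, charge = 0L))
}

dimer_system <- function(r = 0.382, mass = 100) {
  tab <- one_bead_table(mass = mass)
  topo <- build_topology("GG", tab, geometry_sphere(1e6, k_wall = 0))
  list(table = tab, topology = topo,
       positions = rbind(c(0, 0, 0), c(r, 0, 0)))
}

# naive O(N^2) double loop over all pairs, scalar kernels only
brute_force_energy <- function(pos, topo, tab, cutoff = 3.5) {
  n <- topo$n_beads
  E <- 0
  excl <- matrix(FALSE, n, n)
  if (nrow(topo$bonds)) {
    excl[topo$bonds] <- TRUE
    excl[topo$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  for (seg in topo$rigid)
    for (a in seg) for (b in seg) excl[a, b] <- TRUE
  mi <- function(d) {
    if (topo$geometry$kind == "box")
      d - topo$geometry$L * round(d / topo$geometry$L)
    else d
  }
  for (b in seq_len(nrow(topo$bonds))) {
    r <- sqrt(sum(mi(pos[topo$bonds[b, 1], ] - pos[topo$bonds[b, 2], ])^2))
    E <- E + tab$kb * (r - tab$r0)^2
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (excl[i, j]) next
    r <- sqrt(sum(mi(pos[i, ] - pos[j, ])^2))
    if (r > cutoff) next
    ci <- topo$is_crowder[i]; cj <- topo$is_crowder[j]
    if (!ci && !cj) {
      sg <- (topo$sigma[i] + topo$sigma[j]) / 2
      lb <- tab$mu * (topo$lambda0[i] + topo$lambda0[j]) / 2 - tab$delta
      E <- E + vdw_energy(r, sg, lb, tab$epsilon) +
        elec_energy(r, topo$charge[i], topo$charge[j], tab)
    } else if (ci && cj) {
      E <- E + crowder_crowder_energy(r, topo$crowder, tab$epsilon)
    } else {
      E <- E + protein_crowder_energy(r, topo$crowder, tab$epsilon)
    }
  }
  E
}

# naive per-frame contact indicator between two bead sets
brute_force_contacts <- function(pa, pb, sigma_a, sigma_b, geometry,
                                 cutoff_factor = 0.75) {
  M <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    d <- pa[i, ] - pb[j, ]
    if (geometry$kind == "box")
      d <- d - geometry$L * round(d / geometry$L)
    M[i, j] <- sqrt(sum(d^2)) < cutoff_factor * (sigma_a[i] + sigma_b[j])
  }
  M
}

random_crowded_topology <- function(n_res = 24, n_crowd = 4, L = 8,
                                    seed = 1) {
  tab <- toy_table()
  topo <- build_topology(c(strrep("AB", n_res / 4), strrep("EK", n_res / 4)),
                         tab, geometry_box(L, L, L))
  if (n_crowd > 0) {
    cs <- crowder_spec("attractive", r0 = tab$r0)
    topo$n_beads <- topo$n_beads + n_crowd
    topo$chain <- c(topo$chain, rep(NA_integer_, n_crowd))
    topo$local_index <- c(topo$local_index, rep(NA_integer_, n_crowd))
    topo$code <- c(topo$code, rep(NA_character_, n_crowd))
    topo$mass <- c(topo$mass, rep(cs$mass, n_crowd))
    topo$sigma <- c(topo$sigma, rep(2 * cs$r_c, n_crowd))
    topo$lambda0 <- c(topo$lambda0, rep(0, n_crowd))
    topo$charge <- c(topo$charge, rep(0L, n_crowd))
    topo$is_crowder <- c(topo$is_crowder, rep(TRUE, n_crowd))
    topo$crowder <- cs
  }
  topo
}

# random configuration with no near-singular crowder overlaps
random_positions <- function(topo, lo = 1, hi = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(hi))
    hi <- if (topo$geometry$kind == "box") min(topo$geometry$L) - 1 else 5
  repeat {
    pos <- matrix(runif(3 * topo$n_beads, lo, hi), ncol = 3)
    ok <- TRUE
    if (!is.null(topo$crowder)) {
      cr <- which(topo$is_crowder)
      for (i in cr) {
        d <- sqrt(rowSums(sweep(pos[-i, , drop = FALSE], 2, pos[i, ])^2))
        lim <- ifelse(topo$is_crowder[-i], topo$crowder$delta_cc,
                      topo$crowder$delta_pc)
        if (any(d <= lim + 0.05)) { ok <- FALSE; break }
      }
    }
    if (ok) return(pos)
  }
}
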