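# Energy kernels and analytic forces for the coarse-grained model:
# harmonic bonds, hydropathy-modulated Lennard-Jones, Debye-Hueckel
# electrostatics, and shifted inverse-power crowder terms.

#' Harmonic bond energy
#'
#' `kb * (r - r0)^2` (note: no factor 1/2; `kb` absorbs it).
#'
#' @param r Bond length(s), nm; must be positive.
#' @param table An [hps_table()] supplying `kb` and `r0`.
#' @return Energy, kcal/mol.
#' @export
bond_energy <- function(r, table) {
  if (any(r <= 0)) stop("bond length must be positive")
  table$kb * (r - table$r0)^2
}

.lj <- function(r, sigma, epsilon) {
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

.lj_dudr <- function(r, sigma, epsilon) {
  sr6 <- (sigma / r)^6
  4 * epsilon * (-12 * sr6^2 + 6 * sr6) / r
}

#' Hydropathy-modulated van der Waals pair energy
#'
#' Ashbaugh-Hatch form: below the Lennard-Jones minimum
#' `2^(1/6) sigma_ij` the potential is `LJ(r) + (1 - lambda_ij) epsilon`
#' (purely repulsive core, shifted so the two branches meet); beyond it the
#' attractive tail is scaled, `lambda_ij * LJ(r)`. Continuous at the branch
#' point where both forms equal `-lambda_ij * epsilon`.
#'
#' @param r Distance(s), nm.
#' @param sigma_ij Combined contact distance, nm.
#' @param lambda_ij Combined hydropathy (may be slightly negative).
#' @param epsilon Energy scale, kcal/mol.
#' @param cutoff Truncation distance, nm (`Inf` to disable).
#' @return Energy, kcal/mol.
#' @export
vdw_energy <- function(r, sigma_ij, lambda_ij, epsilon = 0.2, cutoff = Inf) {
  if (any(r <= 0)) stop("distance must be positive")
  rmin <- 2^(1 / 6) * sigma_ij
  lj <- .lj(r, sigma_ij, epsilon)
  out <- ifelse(r <= rmin, lj + (1 - lambda_ij) * epsilon, lambda_ij * lj)
  out[r > cutoff] <- 0
  out
}

#' Debye-Hueckel screened electrostatic pair energy
#'
#' `ke * q_i q_j * exp(-kappa r) / (dielectric * r)` with the Coulomb
#' prefactor `ke` of [cg_constants] (kcal nm/mol).
#'
#' @param r Distance(s), nm.
#' @param q_i,q_j Charges in elementary charges.
#' @param table An [hps_table()] supplying `dielectric` and `kappa`.
#' @param cutoff Truncation distance, nm.
#' @return Energy, kcal/mol.
#' @export
elec_energy <- function(r, q_i, q_j, table, cutoff = Inf) {
  if (any(r <= 0)) stop("distance must be positive")
  out <- cg_constants$coulomb * q_i * q_j *
    exp(-table$kappa * r) / (table$dielectric * r)
  out[r > cutoff] <- 0
  out
}

# Shifted inverse-power kernels shared by the crowder terms. The shifted
# distance reading sigma_ref / (r - delta) is used; `x` below is the reduced
# shifted distance. Kept in one place so the functional form is swappable.
.shifted_rep <- function(r, delta, sigma_ref, epsilon) {
  x <- (r - delta) / sigma_ref
  4 * epsilon * x^-12
}

.shifted_rep_dudr <- function(r, delta, sigma_ref, epsilon) {
  x <- (r - delta) / sigma_ref
  -48 * epsilon * x^-13 / sigma_ref
}

.shifted_lj <- function(r, delta, sigma_ref, epsilon) {
  x <- (r - delta) / sigma_ref
  4 * epsilon * (x^-12 - x^-6)
}

.shifted_lj_dudr <- function(r, delta, sigma_ref, epsilon) {
  x <- (r - delta) / sigma_ref
  4 * epsilon * (-12 * x^-13 + 6 * x^-7) / sigma_ref
}

#' Protein-crowder pair energy
#'
#' Shifted inverse-power kernel in the reduced coordinate
#' `x = (r - delta_pc) / sigma_ref`: repulsive crowders give `4 eps x^-12`,
#' attractive crowders the full LJ-like `4 eps (x^-12 - x^-6)`. The shift
#' `delta_pc` accounts for the size difference between a protein bead and a
#' crowder.
#'
#' @param r Distance(s), nm; must exceed `spec$delta_pc`.
#' @param spec A [crowder_spec()].
#' @param epsilon Energy scale, kcal/mol.
#' @param mode Override of `spec$mode`.
#' @param cutoff Truncation distance, nm.
#' @return Energy, kcal/mol.
#' @export
protein_crowder_energy <- function(r, spec, epsilon = 0.2, mode = spec$mode,
                                   cutoff = Inf) {
  if (any(r <= spec$delta_pc))
    stop("distance inside the singular shift delta_pc = ", spec$delta_pc)
  out <- if (mode == "repulsive")
    .shifted_rep(r, spec$delta_pc, spec$sigma_ref, epsilon)
  else
    .shifted_lj(r, spec$delta_pc, spec$sigma_ref, epsilon)
  out[r > cutoff] <- 0
  out
}

#' Crowder-crowder pair energy
#'
#' Purely repulsive `4 eps x^-12` with `x = (r - delta_cc) / sigma_ref`,
#' regardless of the crowder mode: crowders interact with the protein but
#' not attractively with one another.
#'
#' @inheritParams protein_crowder_energy
#' @return Energy, kcal/mol.
#' @export
crowder_crowder_energy <- function(r, spec, epsilon = 0.2, cutoff = Inf) {
  if (any(r <= spec$delta_cc))
    stop("distance inside the singular shift delta_cc = ", spec$delta_cc)
  out <- .shifted_rep(r, spec$delta_cc, spec$sigma_ref, epsilon)
  out[r > cutoff] <- 0
  out
}

# ---------------------------------------------------------------------------
# Pair bookkeeping: enumerate i<j pairs once per topology, tagging each with
# its interaction kind and combined coefficients. Kinds: 1 vdw+elec (protein-
# protein nonbonded), 2 protein-crowder, 3 crowder-crowder; excluded pairs
# (bonded neighbours, intra-rigid) are dropped.

.pair_tables <- function(topology, table) {
  n <- topology$n_beads
  if (n < 2) {
    return(list(i = integer(0), j = integer(0), kind = integer(0),
                sigma = numeric(0), lambda = numeric(0), qq = numeric(0)))
  }
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  excl <- matrix(FALSE, n, n)
  if (nrow(topology$bonds))
    excl[topology$bonds] <- TRUE
  for (seg in topology$rigid) {
    excl[as.matrix(expand.grid(seg, seg))] <- TRUE
  }
  keep <- !excl[cbind(i, j)]
  i <- i[keep]; j <- j[keep]
  ci <- topology$is_crowder[i]; cj <- topology$is_crowder[j]
  kind <- ifelse(!ci & !cj, 1L, ifelse(ci & cj, 3L, 2L))
  list(i = i, j = j, kind = kind,
       sigma = (topology$sigma[i] + topology$sigma[j]) / 2,
       lambda = table$mu * (topology$lambda0[i] + topology$lambda0[j]) / 2 -
         table$delta,
       qq = as.numeric(topology$charge[i]) * as.numeric(topology$charge[j]))
}

.min_image <- function(d, L) d - L * round(d / L)

# displacement vectors i - j under the geometry's boundary conditions
.pair_disp <- function(positions, i, j, geometry) {
  d <- positions[i, , drop = FALSE] - positions[j, , drop = FALSE]
  if (geometry$kind == "box")
    for (k in 1:3) d[, k] <- .min_image(d[, k], geometry$L[k])
  d
}

#' Energy and force evaluator for a fixed topology
#'
#' Precomputes the pair lists and returns a function
#' `function(positions)` yielding `list(energy = <energy_breakdown>,
#' forces = <N x 3 matrix>)`. Directly bonded `(i, i+1)` pairs and pairs
#' inside the same rigid segment are excluded from all nonbonded terms; the
#' minimum-image convention applies in periodic boxes; all nonbonded terms
#' are plainly truncated at `cutoff`. In spherical geometry a harmonic wall
#' force (zero inside the radius) is added.
#'
#' @param topology A `cg_topology`.
#' @param table An [hps_table()].
#' @param cutoff Nonbonded truncation distance, nm.
#' @param include Character subset of `c("bond", "vdw", "elec", "crowder",
#'   "wall")` to evaluate; the default includes everything.
#' @return A function of a positions matrix.
#' @export
make_energy_force <- function(topology, table, cutoff = 3.5,
                              include = c("bond", "vdw", "elec", "crowder",
                                          "wall")) {
  pt <- .pair_tables(topology, table)
  bonds <- topology$bonds
  geometry <- topology$geometry
  spec <- topology$crowder
  eps <- table$epsilon
  n <- topology$n_beads
  do_bond <- "bond" %in% include && nrow(bonds) > 0
  do_vdw <- "vdw" %in% include
  do_elec <- "elec" %in% include
  do_crowd <- "crowder" %in% include && !is.null(spec)
  do_wall <- "wall" %in% include && geometry$kind == "sphere"

  function(positions) {
    stopifnot(nrow(positions) == n)
    F <- matrix(0, n, 3)
    e <- c(bond = 0, vdw = 0, elec = 0, protein_crowder = 0,
           crowder_crowder = 0, wall = 0)

    add_pair_forces <- function(F, ii, jj, dudr, d, r) {
      # F_i = -dU/dr * (d / r); accumulate with duplicate-safe rowsum
      w <- -dudr / r
      fx <- w * d[, 1]; fy <- w * d[, 2]; fz <- w * d[, 3]
      for (s in 1:2) {
        idx <- if (s == 1) ii else jj
        sgn <- if (s == 1) 1 else -1
        sm <- rowsum(cbind(fx, fy, fz) * sgn, group = idx)
        rows <- as.integer(rownames(sm))
        F[rows, ] <- F[rows, , drop = FALSE] + sm
      }
      F
    }

    if (do_bond) {
      d <- .pair_disp(positions, bonds[, 1], bonds[, 2], geometry)
      r <- sqrt(rowSums(d^2))
      if (any(r <= 0)) stop("coincident bonded beads")
      e["bond"] <- sum(table$kb * (r - table$r0)^2)
      F <- add_pair_forces(F, bonds[, 1], bonds[, 2],
                           2 * table$kb * (r - table$r0), d, r)
    }

    if (length(pt$i)) {
      d <- .pair_disp(positions, pt$i, pt$j, geometry)
      r2 <- rowSums(d^2)
      act <- which(r2 < cutoff^2)
      if (length(act)) {
        r <- sqrt(r2[act])
        ii <- pt$i[act]; jj <- pt$j[act]; kind <- pt$kind[act]
        da <- d[act, , drop = FALSE]
        dudr <- numeric(length(act))
        u <- numeric(length(act))

        pp <- kind == 1L
        if (any(pp) && (do_vdw || do_elec)) {
          sg <- pt$sigma[act][pp]; lb <- pt$lambda[act][pp]
          rp <- r[pp]
          if (do_vdw) {
            rmin <- 2^(1 / 6) * sg
            core <- rp <= rmin
            lj <- .lj(rp, sg, eps); ljd <- .lj_dudr(rp, sg, eps)
            u_v <- ifelse(core, lj + (1 - lb) * eps, lb * lj)
            d_v <- ifelse(core, ljd, lb * ljd)
            e["vdw"] <- sum(u_v)
            u[pp] <- u[pp] + u_v; dudr[pp] <- dudr[pp] + d_v
          }
          if (do_elec) {
            qq <- pt$qq[act][pp]
            ch <- qq != 0
            if (any(ch)) {
              rq <- rp[ch]
              u_e <- cg_constants$coulomb * qq[ch] *
                exp(-table$kappa * rq) / (table$dielectric * rq)
              d_e <- -u_e * (table$kappa + 1 / rq)
              e["elec"] <- sum(u_e)
              idx <- which(pp)[ch]
              u[idx] <- u[idx] + u_e; dudr[idx] <- dudr[idx] + d_e
            }
          }
        }

        if (do_crowd) {
          pc <- kind == 2L
          if (any(pc)) {
            rp <- r[pc]
            if (any(rp <= spec$delta_pc)) {
              bad <- which(pc)[rp <= spec$delta_pc][1]
              stop("singular protein-crowder distance between beads ",
                   ii[bad], " and ", jj[bad])
            }
            if (spec$mode == "repulsive") {
              u_c <- .shifted_rep(rp, spec$delta_pc, spec$sigma_ref, eps)
              d_c <- .shifted_rep_dudr(rp, spec$delta_pc, spec$sigma_ref, eps)
            } else {
              u_c <- .shifted_lj(rp, spec$delta_pc, spec$sigma_ref, eps)
              d_c <- .shifted_lj_dudr(rp, spec$delta_pc, spec$sigma_ref, eps)
            }
            e["protein_crowder"] <- sum(u_c)
            u[pc] <- u[pc] + u_c; dudr[pc] <- dudr[pc] + d_c
          }
          cc <- kind == 3L
          if (any(cc)) {
            rp <- r[cc]
            if (any(rp <= spec$delta_cc)) {
              bad <- which(cc)[rp <= spec$delta_cc][1]
              stop("singular crowder-crowder distance between beads ",
                   ii[bad], " and ", jj[bad])
            }
            u_c <- .shifted_rep(rp, spec$delta_cc, spec$sigma_ref, eps)
            d_c <- .shifted_rep_dudr(rp, spec$delta_cc, spec$sigma_ref, eps)
            e["crowder_crowder"] <- sum(u_c)
            u[cc] <- u[cc] + u_c; dudr[cc] <- dudr[cc] + d_c
          }
        }

        nz <- dudr != 0
        if (any(nz))
          F <- add_pair_forces(F, ii[nz], jj[nz], dudr[nz],
                               da[nz, , drop = FALSE], r[nz])
      }
    }

    if (do_wall) {
      rad <- sqrt(rowSums(positions^2))
      out <- rad > geometry$radius
      if (any(out)) {
        exc <- rad[out] - geometry$radius
        e["wall"] <- sum(0.5 * geometry$k_wall * exc^2)
        F[out, ] <- F[out, , drop = FALSE] -
          geometry$k_wall * exc / rad[out] * positions[out, , drop = FALSE]
      }
    }

    breakdown <- structure(as.list(c(e, total = sum(e))),
                           class = "energy_breakdown")
    list(energy = breakdown, forces = F)
  }
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kcal/mol):\n")
  for (nm in setdiff(names(x), "total"))
    cat(sprintf("  %-16s %12.6g\n", nm, x[[nm]]))
  cat(sprintf("  %-16s %12.6g\n", "total", x$total))
  invisible(x)
}

#' Total potential energy of a configuration
#'
#' Sums every applicable pair term (bonds, hydropathy-scaled vdW,
#' Debye-Hueckel electrostatics, crowder kernels, confinement wall) with
#' minimum-image distances in periodic boxes, plain truncation at `cutoff`,
#' and exclusion of bonded neighbours and intra-rigid pairs.
#'
#' @param positions N x 3 matrix, nm.
#' @param topology A `cg_topology`.
#' @param table An [hps_table()].
#' @param cutoff Nonbonded truncation, nm.
#' @return An `energy_breakdown` (list of components plus `total`).
#' @export
total_energy <- function(positions, topology, table, cutoff = 3.5) {
  make_energy_force(topology, table, cutoff)(positions)$energy
}

#' Analytic forces on every bead
#'
#' Negative gradient of [total_energy()]; net force on the whole system is
#' zero in open geometry (pairwise interactions only).
#'
#' @inheritParams total_energy
#' @return N x 3 matrix, kcal/(mol nm).
#' @export
forces <- function(positions, topology, table, cutoff = 3.5) {
  make_energy_force(topology, table, cutoff)(positions)$forces
}

#' @method tidy energy_breakdown
#' @export
tidy.energy_breakdown <- function(x, ...) {
  tibble::tibble(term = names(x), energy = unlist(x, use.names = FALSE))
}
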