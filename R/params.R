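# Force-field parameter tables, pair-combination rules, crowder specs,
# region bookkeeping and system topology assembly.

#' Build an HPS force-field parameter table
#'
#' Assembles the per-residue parameters and the global force-field constants
#' of the hydropathy-scale (HPS-Urry) coarse-grained model: one bead per
#' residue, harmonic bonds, a hydropathy-modulated Lennard-Jones term and
#' Debye-Hueckel screened electrostatics. The effective pair hydropathy is
#' the affine map `lambda_ij = mu * (lambda0_i + lambda0_j)/2 - delta`.
#'
#' @param residues data frame with columns `code` (one-letter identifier),
#'   `mass` (amu), `sigma` (vdW diameter, nm), `lambda0` (dimensionless
#'   hydropathy in `[0, 1.2]`) and `charge` (integer -1, 0 or +1).
#' @param mu,delta Hydropathy rescaling slope and offset (dimensionless).
#' @param epsilon Pairwise energy scale, kcal/mol.
#' @param kb Bond spring constant, kcal/(mol nm^2); the bond energy is
#'   `kb * (r - r0)^2` (no 1/2).
#' @param r0 Equilibrium bond length, nm.
#' @param dielectric Relative solvent dielectric constant.
#' @param kappa Inverse Debye screening length, 1/nm (1.0 corresponds to
#'   roughly 100 mM monovalent salt).
#' @return An object of class `hps_table`.
#' @export
#' @examples
#' tab <- default_hps_table()
#' combine_pair("F", "E", tab)
hps_table <- function(residues, mu = 1.0, delta = 0.08, epsilon = 0.2,
                      kb = 1000, r0 = 0.382, dielectric = 80, kappa = 1.0) {
  need <- c("code", "mass", "sigma", "lambda0", "charge")
  if (!is.data.frame(residues) || !all(need %in% names(residues)))
    stop("`residues` must be a data frame with columns ",
         paste(need, collapse = ", "))
  residues <- as.data.frame(residues)[, need]
  residues$code <- as.character(residues$code)
  if (anyDuplicated(residues$code))
    stop("duplicated residue codes in parameter table")
  if (any(residues$sigma <= 0) || any(residues$mass <= 0))
    stop("sigma and mass must be strictly positive")
  if (!all(residues$charge %in% c(-1L, 0L, 1L)))
    stop("charges must be integers in {-1, 0, +1}")
  if (any(residues$lambda0 < 0 | residues$lambda0 > 1.2))
    stop("lambda0 must lie in [0, 1.2]")
  # fixed protonation rule at pH 7: R,K -> +1; D,E -> -1; H and others -> 0
  rule <- c(R = 1L, K = 1L, D = -1L, E = -1L, H = 0L)
  known <- intersect(residues$code, names(rule))
  bad <- known[residues$charge[match(known, residues$code)] != rule[known]]
  if (length(bad))
    stop("charge of residue(s) ", paste(bad, collapse = ", "),
         " contradicts the fixed protonation rule (R,K = +1; D,E = -1; H = 0)")
  consts <- c(mu = mu, delta = delta, epsilon = epsilon, kb = kb, r0 = r0,
              dielectric = dielectric, kappa = kappa)
  if (any(consts[c("mu", "epsilon", "kb", "r0", "dielectric", "kappa")] <= 0))
    stop("force-field constants must be strictly positive")
  rownames(residues) <- residues$code
  structure(list(residues = residues, mu = mu, delta = delta,
                 epsilon = epsilon, kb = kb, r0 = r0,
                 dielectric = dielectric, kappa = kappa),
            class = "hps_table")
}

#' @export
print.hps_table <- function(x, ...) {
  cat("HPS parameter table:", nrow(x$residues), "residue types\n")
  cat(sprintf("  mu = %g, delta = %g, epsilon = %g kcal/mol\n",
              x$mu, x$delta, x$epsilon))
  cat(sprintf("  kb = %g kcal/(mol nm^2), r0 = %g nm\n", x$kb, x$r0))
  cat(sprintf("  dielectric = %g, kappa = %g 1/nm\n", x$dielectric, x$kappa))
  invisible(x)
}

#' Read a per-residue parameter table from a TSV file
#'
#' The file is tab-separated with comment lines starting `#` and columns
#' `code`, `mass`, `sigma`, `lambda0`, `charge` (see
#' [default_hps_table()] for the packaged example).
#'
#' @param path Path to the TSV file.
#' @param ... Passed on to [hps_table()] (force-field constants).
#' @return An `hps_table`.
#' @export
read_hps_params <- function(path, ...) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  hps_table(df, ...)
}

#' The packaged HPS-Urry parameter set
#'
#' Loads the default per-residue table shipped with the package
#' (`extdata/hps_urry_params.tsv`). The file is an ordinary editable TSV;
#' alternative parameter sets can be supplied through [read_hps_params()].
#'
#' @param ... Force-field constants passed to [hps_table()].
#' @return An `hps_table` with the 20 standard amino acids.
#' @export
default_hps_table <- function(...) {
  read_hps_params(system.file("extdata", "hps_urry_params.tsv",
                              package = "crowdsep", mustWork = TRUE), ...)
}

.lookup_residues <- function(codes, table) {
  idx <- match(codes, table$residues$code)
  if (anyNA(idx))
    stop("unknown residue code(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  table$residues[idx, , drop = FALSE]
}

#' Combine two residues' parameters into pair coefficients
#'
#' Applies the Lorentz rule for the contact distance,
#' `sigma_ij = (sigma_i + sigma_j)/2`, and the hydropathy map
#' `lambda_ij = mu * (lambda0_i + lambda0_j)/2 - delta`. The combined
#' lambda may be slightly negative and is used as-is.
#'
#' @param i,j One-letter residue codes (vectorised).
#' @param table An [hps_table()].
#' @return A data frame with columns `sigma` (nm) and `lambda`.
#' @export
combine_pair <- function(i, j, table) {
  pi <- .lookup_residues(i, table)
  pj <- .lookup_residues(j, table)
  data.frame(sigma  = (pi$sigma + pj$sigma) / 2,
             lambda = table$mu * (pi$lambda0 + pj$lambda0) / 2 - table$delta)
}

#' Define a spherical crowder species
#'
#' Crowders are single spherical beads emulating a PEG1500-like
#' macromolecule. The protein-crowder and crowder-crowder kernels are
#' shifted inverse-power potentials; the shift parameters are derived, not
#' free: `delta_pc = r0/2 + r_c - sigma_ref` and
#' `delta_cc = 2 r_c - sigma_ref`.
#'
#' @param mode `"repulsive"` (excluded volume only) or `"attractive"`
#'   (LJ-like attraction to protein beads). Crowder-crowder interactions are
#'   always purely repulsive.
#' @param mass Crowder mass, amu.
#' @param r_c Crowder radius, nm.
#' @param sigma_ref Reference diameter of the shifted kernels, nm.
#' @param r0 Protein equilibrium bond length used in the shift, nm.
#' @return An object of class `crowder_spec`.
#' @export
#' @examples
#' crowder_spec("repulsive")$delta_pc  # 0.391 nm
crowder_spec <- function(mode = c("repulsive", "attractive"), mass = 1500,
                         r_c = 0.8, sigma_ref = 0.6, r0 = 0.382) {
  mode <- match.arg(mode)
  if (mass <= 0 || r_c <= 0 || sigma_ref <= 0)
    stop("crowder mass, radius and sigma_ref must be positive")
  structure(list(mode = mode, mass = mass, r_c = r_c, sigma_ref = sigma_ref,
                 delta_pc = r0 / 2 + r_c - sigma_ref,
                 delta_cc = 2 * r_c - sigma_ref),
            class = "crowder_spec")
}

#' Number of crowders realising a target volume fraction
#'
#' Inverts the volume-fraction relation `C = N * (4/3) pi r_c^3 / V` under
#' the floor convention: `N = floor(C V / ((4/3) pi r_c^3))`, so the realised
#' fraction never exceeds the request and differs from it by at most one
#' bead volume over `V`.
#'
#' @param C Target volume fraction in `[0, 0.74)`.
#' @param V System volume, nm^3.
#' @param r_c Crowder radius, nm.
#' @return Integer crowder count.
#' @export
#' @examples
#' crowder_count_for_fraction(0.05, 15 * 15 * 50)  # 262
#' crowder_count_for_fraction(0.10, 25^3)          # 728
crowder_count_for_fraction <- function(C, V, r_c = 0.8) {
  if (any(C < 0) || any(C >= 0.74))
    stop("volume fraction must lie in [0, 0.74)")
  if (any(V <= 0)) stop("volume must be positive")
  as.integer(floor(C * V / ((4 / 3) * pi * r_c^3)))
}

#' Box and sphere geometries
#'
#' `geometry_box()` describes a fully periodic orthorhombic box;
#' `geometry_sphere()` describes open space with a harmonic spherical
#' confinement wall.
#'
#' @param Lx,Ly,Lz Box edge lengths, nm.
#' @param radius Confinement radius, nm.
#' @param k_wall Wall stiffness, kcal/(mol nm^2).
#' @return A `cg_geometry` object.
#' @export
geometry_box <- function(Lx, Ly, Lz = Lx) {
  if (any(c(Lx, Ly, Lz) <= 0)) stop("box dimensions must be positive")
  structure(list(kind = "box", L = c(Lx, Ly, Lz)), class = "cg_geometry")
}

#' @rdname geometry_box
#' @export
geometry_sphere <- function(radius, k_wall = 10) {
  if (radius <= 0) stop("radius must be positive")
  structure(list(kind = "sphere", radius = radius, k_wall = k_wall),
            class = "cg_geometry")
}

#' @export
print.cg_geometry <- function(x, ...) {
  if (x$kind == "box")
    cat(sprintf("periodic box %g x %g x %g nm\n", x$L[1], x$L[2], x$L[3]))
  else
    cat(sprintf("spherical confinement, radius %g nm\n", x$radius))
  invisible(x)
}

.geometry_volume <- function(geometry) {
  if (geometry$kind == "box") prod(geometry$L)
  else (4 / 3) * pi * geometry$radius^3
}

#' Region decomposition of a chain
#'
#' A named contiguous residue range carrying both full-protein numbering and
#' 1-based local indices within the simulated chain.
#'
#' @param name Region label.
#' @param global_range Length-2 inclusive residue numbers in full-protein
#'   numbering.
#' @param offset First full-protein residue number of the chain (local index
#'   1 maps to this number).
#' @return A `region_spec` object.
#' @export
region_spec <- function(name, global_range, offset) {
  global_range <- as.integer(global_range)
  if (length(global_range) != 2 || global_range[2] < global_range[1])
    stop("global_range must be an increasing pair")
  local <- global_range - offset + 1L
  if (local[1] < 1L) stop("global_range starts before the chain offset")
  structure(list(name = name, global_range = global_range,
                 local_range = local),
            class = "region_spec")
}

#' The three-region decomposition of the TDP-43 C-terminal domain
#'
#' The simulated chain is the 148-residue CTD (full-protein residues
#' 267-414), partitioned into the disordered IDR1 (267-318), the conserved
#' alpha-helical segment (319-341, simulated as a rigid body) and the
#' disordered IDR2 (342-414).
#'
#' @return Named list of three [region_spec()] objects.
#' @export
tdp43_ctd_regions <- function() {
  list(IDR1  = region_spec("IDR1",  c(267L, 318L), 267L),
       Helix = region_spec("Helix", c(319L, 341L), 267L),
       IDR2  = region_spec("IDR2",  c(342L, 414L), 267L))
}

#' Assemble a simulation topology
#'
#' Collects chains (with per-bead force-field parameters), optional rigid
#' segments, crowders at a target volume fraction and the system geometry
#' into one bookkeeping object. The crowder count is computed from the
#' geometry volume via [crowder_count_for_fraction()].
#'
#' @param sequences Character vector of one-letter sequences (one per chain),
#'   or a named vector as returned by [read_sequences()].
#' @param table An [hps_table()].
#' @param geometry A [geometry_box()] or [geometry_sphere()].
#' @param crowder_mode `NULL` for no crowders, else `"repulsive"` or
#'   `"attractive"`.
#' @param crowder_fraction Target crowder volume fraction.
#' @param crowder Optional [crowder_spec()]; built from `crowder_mode`
#'   when omitted.
#' @param rigid_ranges Optional list of integer pairs `c(first, last)` of
#'   1-based local indices held internally rigid; recycled across chains if
#'   a single range is given, or a list of per-chain lists.
#' @param regions Optional named list of [region_spec()] (applies to every
#'   chain).
#' @return A `cg_topology` with per-bead vectors `mass`, `sigma`, `lambda0`,
#'   `charge`, `chain` (NA for crowders), `local_index`, `is_crowder`, plus
#'   `bonds` (2-column matrix), `rigid` (list of bead-index vectors),
#'   `geometry`, `crowder` and `n_beads`.
#' @export
build_topology <- function(sequences, table, geometry,
                           crowder_mode = NULL, crowder_fraction = 0,
                           crowder = NULL, rigid_ranges = NULL,
                           regions = NULL) {
  if (length(sequences) < 1 && is.null(crowder_mode) && crowder_fraction == 0)
    stop("empty system: no chains and no crowders")
  stopifnot(inherits(table, "hps_table"), inherits(geometry, "cg_geometry"))
  seqs <- lapply(sequences, function(s) strsplit(toupper(s), "")[[1]])
  lens <- vapply(seqs, length, integer(1))

  chain <- rep(seq_along(seqs), lens)
  local_index <- unlist(lapply(lens, seq_len), use.names = FALSE)
  codes <- unlist(seqs, use.names = FALSE)
  pars <- if (length(codes)) .lookup_residues(codes, table) else
    data.frame(mass = numeric(0), sigma = numeric(0),
               lambda0 = numeric(0), charge = integer(0))

  n_prot <- length(codes)
  n_crowd <- 0L
  if (!is.null(crowder_mode) || !is.null(crowder)) {
    if (is.null(crowder)) crowder <- crowder_spec(crowder_mode, r0 = table$r0)
    n_crowd <- crowder_count_for_fraction(crowder_fraction,
                                          .geometry_volume(geometry),
                                          crowder$r_c)
  }

  # bonds: consecutive beads within each chain
  bonds <- do.call(rbind, lapply(seq_along(lens), function(k) {
    if (lens[k] < 2) return(NULL)
    off <- if (k == 1) 0L else sum(lens[seq_len(k - 1)])
    cbind(off + seq_len(lens[k] - 1L), off + seq_len(lens[k] - 1L) + 1L)
  }))
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)

  # rigid segments -> global bead index vectors
  rigid <- list()
  if (!is.null(rigid_ranges)) {
    if (is.numeric(rigid_ranges)) rigid_ranges <- list(rigid_ranges)
    per_chain <- if (all(vapply(rigid_ranges, is.numeric, logical(1))))
      rep(list(rigid_ranges), length(seqs)) else rigid_ranges
    if (length(per_chain) != length(seqs))
      stop("rigid_ranges must give one range set per chain (or one shared)")
    for (k in seq_along(per_chain)) {
      off <- if (k == 1) 0L else sum(lens[seq_len(k - 1)])
      for (rg in per_chain[[k]]) {
        rg <- as.integer(rg)
        if (length(rg) != 2 || rg[1] < 1 || rg[2] > lens[k] || rg[1] > rg[2])
          stop("rigid range [", rg[1], ", ", rg[2],
               "] outside chain ", k, " (length ", lens[k], ")")
        rigid[[length(rigid) + 1L]] <- off + rg[1]:rg[2]
      }
    }
  }

  topo <- structure(list(
    n_beads = n_prot + n_crowd,
    n_chains = length(seqs),
    chain_lengths = lens,
    chain = c(chain, rep(NA_integer_, n_crowd)),
    local_index = c(local_index, rep(NA_integer_, n_crowd)),
    code = c(codes, rep(NA_character_, n_crowd)),
    mass = c(pars$mass, rep(if (n_crowd) crowder$mass else numeric(0),
                            n_crowd)),
    sigma = c(pars$sigma, rep(if (n_crowd) 2 * crowder$r_c else numeric(0),
                              n_crowd)),
    lambda0 = c(pars$lambda0, rep(0, n_crowd)),
    charge = c(pars$charge, rep(0L, n_crowd)),
    is_crowder = c(rep(FALSE, n_prot), rep(TRUE, n_crowd)),
    bonds = bonds,
    rigid = rigid,
    crowder = if (n_crowd) crowder else NULL,
    geometry = geometry,
    regions = regions
  ), class = "cg_topology")
  topo
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("CG topology: %d beads (%d chains, %d crowders%s)\n",
              x$n_beads, x$n_chains, sum(x$is_crowder),
              if (!is.null(x$crowder)) paste0(", ", x$crowder$mode) else ""))
  print(x$geometry)
  if (length(x$rigid))
    cat("  rigid segments:", length(x$rigid), "\n")
  invisible(x)
}

#' Beads belonging to one chain
#'
#' @param topology A `cg_topology`.
#' @param chain Chain index.
#' @return Integer vector of global bead indices.
#' @export
chain_beads <- function(topology, chain) {
  which(!topology$is_crowder & topology$chain == chain)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [seqinr::read.fasta()] returning upper-case
#' one-letter strings, one per record.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  out <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  names(out) <- names(recs)
  out
}
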