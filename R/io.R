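# File formats, run configuration and result export. Package-internal unit
# contract is nm/ps/kcal/mol; LAMMPS-dump files ("real" units, Angstrom)
# are converted at this boundary only.

.ANG_PER_NM <- 10

#' Read a trajectory file
#'
#' Supported formats: extended XYZ (comment line `time=<ps> box=<Lx,Ly,Lz>`
#' in nm, as written by [write_trajectory()]) and LAMMPS dump (`atom`
#' style: `id type x y z` with box bounds; coordinates in Angstrom,
#' converted to nm on read). The bead count must be constant across frames.
#'
#' @param path File path.
#' @param format `"xyz"` or `"lammps_dump"`.
#' @param topology Optional `cg_topology` to attach; a minimal
#'   single-species stand-in is built when omitted.
#' @return A `cg_trajectory` (attribute `units_in` records the on-disk
#'   unit).
#' @export
read_trajectory <- function(path, format = c("xyz", "lammps_dump"),
                            topology = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  frames <- if (format == "xyz") .parse_xyz(lines) else .parse_dump(lines)
  n <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(n)) != 1)
    stop("inconsistent bead counts across frames (frame ",
         which(n != n[1])[1], " has ", n[n != n[1]][1], ", expected ",
         n[1], ")")
  if (is.null(topology))
    topology <- .fixture_topology(n[1], 1L, frames[[1]]$box)
  traj <- new_trajectory(frames, topology)
  attr(traj, "units_in") <- if (format == "xyz") "nm" else "angstrom"
  traj
}

.parse_xyz <- function(lines) {
  frames <- list()
  k <- 1L
  fi <- 0L
  while (k <= length(lines)) {
    if (!nzchar(trimws(lines[k]))) { k <- k + 1L; next }
    fi <- fi + 1L
    n <- suppressWarnings(as.integer(trimws(lines[k])))
    if (is.na(n)) stop("malformed atom count at line ", k)
    if (k + 1L + n > length(lines))
      stop("truncated frame ", fi, ": expected ", n, " atoms")
    comment <- lines[k + 1L]
    tm <- .field_num(comment, "time")
    bx <- .field_num(comment, "box", 3)
    box <- if (!anyNA(bx)) geometry_box(bx[1], bx[2], bx[3])
           else geometry_box(1e6, 1e6, 1e6)
    body <- lines[(k + 2L):(k + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stop("malformed atom record in frame ", fi, " (atom ", bad[1], ")")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("non-numeric coordinates in frame ", fi)
    frames[[fi]] <- list(time = if (is.na(tm)) fi - 1 else tm,
                         positions = xyz, box = box)
    k <- k + 2L + n
  }
  if (!length(frames)) stop("no frames found")
  frames
}

.field_num <- function(s, key, n = 1) {
  m <- regmatches(s, regexpr(paste0(key, "=[-0-9eE+.,]+"), s))
  if (!length(m)) return(rep(NA_real_, n))
  as.numeric(strsplit(sub(paste0(key, "="), "", m), ",")[[1]])[seq_len(n)]
}

.parse_dump <- function(lines) {
  its <- grep("^ITEM: TIMESTEP", lines)
  if (!length(its)) stop("not a LAMMPS dump file: no ITEM: TIMESTEP")
  frames <- vector("list", length(its))
  bounds_end <- c(its[-1] - 1L, length(lines))
  for (fi in seq_along(its)) {
    block <- lines[its[fi]:bounds_end[fi]]
    step <- as.numeric(block[2])
    nat_i <- grep("^ITEM: NUMBER OF ATOMS", block)[1]
    n <- as.integer(block[nat_i + 1L])
    bb_i <- grep("^ITEM: BOX BOUNDS", block)[1]
    bb <- do.call(rbind, lapply(block[bb_i + 1:3], function(l)
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]][1:2])))
    at_i <- grep("^ITEM: ATOMS", block)[1]
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", block[at_i]),
                     "[[:space:]]+")[[1]]
    need <- match(c("id", "x", "y", "z"), cols)
    if (anyNA(need))
      stop("dump frame ", fi, " lacks id/x/y/z columns")
    if (at_i + n > length(block))
      stop("truncated dump frame ", fi, ": expected ", n, " atoms")
    rows <- strsplit(trimws(block[at_i + seq_len(n)]), "[[:space:]]+")
    M <- t(vapply(rows, function(p) as.numeric(p[need]), numeric(4)))
    M <- M[order(M[, 1]), , drop = FALSE]
    Lbox <- (bb[, 2] - bb[, 1]) / .ANG_PER_NM
    frames[[fi]] <- list(
      time = step,
      positions = sweep(M[, 2:4, drop = FALSE] / .ANG_PER_NM, 2,
                        bb[, 1] / .ANG_PER_NM),
      box = geometry_box(Lbox[1], Lbox[2], Lbox[3]))
  }
  frames
}

#' Write a trajectory file
#'
#' XYZ frames carry `time=` (ps) and `box=` (nm) on the comment line and
#' coordinates in nm; LAMMPS dump frames are written in Angstrom (`atom`
#' style columns `id type x y z`).
#'
#' @param traj A `cg_trajectory`.
#' @param path Output path.
#' @param format `"xyz"` or `"lammps_dump"`.
#' @param digits Coordinate precision (significant decimals).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "lammps_dump"),
                             digits = 6) {
  format <- match.arg(format)
  topo <- traj$topology
  type <- ifelse(topo$is_crowder, 2L, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(traj$frames)) {
    f <- traj$frames[[fi]]
    n <- nrow(f$positions)
    if (format == "xyz") {
      bx <- if (f$box$kind == "box")
        paste0(" box=", paste(signif(f$box$L, 10), collapse = ",")) else ""
      writeLines(c(as.character(n),
                   paste0("time=", signif(f$time, 10), bx)), con)
      writeLines(sprintf(paste0("%s %.", digits, "f %.", digits,
                                "f %.", digits, "f"),
                         ifelse(topo$is_crowder, "C", "P"),
                         f$positions[, 1], f$positions[, 2],
                         f$positions[, 3]), con)
    } else {
      L <- if (f$box$kind == "box") f$box$L else rep(2 * f$box$radius, 3)
      writeLines(c("ITEM: TIMESTEP", format(f$time, scientific = FALSE),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   "ITEM: BOX BOUNDS pp pp pp",
                   sprintf("0 %.6f", L * .ANG_PER_NM),
                   "ITEM: ATOMS id type x y z"), con)
      writeLines(sprintf(paste0("%d %d %.", digits, "f %.", digits,
                                "f %.", digits, "f"),
                         seq_len(n), type,
                         f$positions[, 1] * .ANG_PER_NM,
                         f$positions[, 2] * .ANG_PER_NM,
                         f$positions[, 3] * .ANG_PER_NM), con)
    }
  }
  invisible(path)
}

#' Export a topology as a LAMMPS data file
#'
#' Writes an `atom_style bond` data file (masses per type, atoms, bonds for
#' chain connectivity) in Angstrom, as a convenience for cross-checking
#' against an external engine.
#'
#' @param topology A `cg_topology` with box geometry.
#' @param positions N x 3 matrix, nm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_lammps_data <- function(topology, positions, path) {
  if (topology$geometry$kind != "box")
    stop("LAMMPS data export needs a periodic box")
  codes <- unique(stats::na.omit(topology$code))
  type_of <- function(k) {
    if (topology$is_crowder[k]) length(codes) + 1L
    else match(topology$code[k], codes)
  }
  types <- vapply(seq_len(topology$n_beads), type_of, integer(1))
  ntypes <- max(types)
  mass_of_type <- vapply(seq_len(ntypes), function(t)
    topology$mass[which(types == t)[1]], numeric(1))
  L <- topology$geometry$L * .ANG_PER_NM
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("LAMMPS data file (coarse-grained beads)", "",
               paste(topology$n_beads, "atoms"),
               paste(nrow(topology$bonds), "bonds"),
               paste(ntypes, "atom types"),
               paste(if (nrow(topology$bonds)) 1 else 0, "bond types"), "",
               sprintf("0 %.6f xlo xhi", L[1]),
               sprintf("0 %.6f ylo yhi", L[2]),
               sprintf("0 %.6f zlo zhi", L[3]), "", "Masses", ""), con)
  writeLines(sprintf("%d %.4f", seq_len(ntypes), mass_of_type), con)
  writeLines(c("", "Atoms # bond", ""), con)
  mol <- ifelse(is.na(topology$chain), 0L, topology$chain)
  writeLines(sprintf("%d %d %d %.6f %.6f %.6f",
                     seq_len(topology$n_beads), mol, types,
                     positions[, 1] * .ANG_PER_NM,
                     positions[, 2] * .ANG_PER_NM,
                     positions[, 3] * .ANG_PER_NM), con)
  if (nrow(topology$bonds)) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(sprintf("%d 1 %d %d", seq_len(nrow(topology$bonds)),
                       topology$bonds[, 1], topology$bonds[, 2]), con)
  }
  invisible(path)
}

# --- run configuration ------------------------------------------------------

.config_schema <- list(
  sequences = "character", fasta = "character", param_table = "character",
  geometry = "list", crowder = "list", integrator = "list",
  protocol = "character", slab = "list", ladder = "list",
  observables = "list", rigid_ranges = "list", seed = "numeric",
  output_dir = "character")

.config_defaults <- list(
  protocol = "slab",
  integrator = list(timestep = 0.01, temperature = 300, damping = 1000,
                    output_stride = 10000),
  observables = list(), seed = 1, output_dir = ".")

#' Read and validate a YAML run configuration
#'
#' Unknown top-level keys are rejected; defaults are materialised so the
#' returned object is fully resolved (and is what [write_results()] copies
#' into the output directory for provenance).
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(.config_defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- .config_defaults[[nm]]
  for (nm in names(.config_defaults$integrator))
    if (is.null(cfg$integrator[[nm]]))
      cfg$integrator[[nm]] <- .config_defaults$integrator[[nm]]
  if (is.null(cfg$sequences) && is.null(cfg$fasta))
    stop("config must provide `sequences` or `fasta`")
  structure(cfg, class = "run_config")
}

#' Write analysis results to a directory
#'
#' Deterministic file naming: matrices and data frames become TSV files
#' with `#`-prefixed header metadata, everything else is collected into
#' `summary.json`. A `manifest.tsv` lists every artifact with its MD5
#' content hash; reruns with the same inputs produce identical hashes.
#'
#' @param results Named list. Matrix/data-frame elements are written as
#'   `<name>.tsv`; scalar/list elements go into the JSON summary.
#' @param out_dir Output directory (created if needed).
#' @param meta Optional named list of metadata written into every TSV
#'   header and the summary (units, frame windows, seeds, ...).
#' @return Data frame manifest (`file`, `md5`), invisibly.
#' @export
write_results <- function(results, out_dir, meta = list()) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (length(results) && is.null(names(results)))
    stop("results must be a named list")
  files <- character(0)
  summary <- list()
  hdr <- vapply(names(meta), function(k)
    paste0("# ", k, ": ", paste(format(meta[[k]]), collapse = " ")),
    character(1))
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x) || is.data.frame(x)) {
      fp <- file.path(out_dir, paste0(nm, ".tsv"))
      con <- file(fp, "w")
      writeLines(unname(hdr), con)
      write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      close(con)
      files <- c(files, fp)
    } else summary[[nm]] <- x
  }
  summary$meta <- meta
  fp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, fp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, fp)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @importFrom utils write.table
NULL
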