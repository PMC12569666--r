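# Trajectory container shared by the dynamics, fixtures and analysis layers.

#' Construct a trajectory object
#'
#' A `cg_trajectory` is a list of frames (each `list(time, positions, box)`,
#' positions in nm, time in ps) plus the topology they belong to. Frames
#' must be in strictly increasing time order.
#'
#' @param frames List of frames.
#' @param topology The `cg_topology` the frames describe.
#' @return A `cg_trajectory`.
#' @export
new_trajectory <- function(frames, topology) {
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  for (f in frames) {
    if (!all(is.finite(f$positions)))
      stop("non-finite coordinates in frame at t = ", f$time)
    if (nrow(f$positions) != topology$n_beads)
      stop("frame bead count does not match topology")
  }
  structure(list(frames = frames, topology = topology),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("CG trajectory: %d frames, %d beads", n, x$topology$n_beads))
  if (n) cat(sprintf(", t = %g..%g ps", x$frames[[1]]$time,
                     x$frames[[n]]$time))
  cat("\n")
  invisible(x)
}

#' @export
length.cg_trajectory <- function(x) length(x$frames)

#' Frame times of a trajectory
#' @param traj A `cg_trajectory`.
#' @return Numeric vector, ps.
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, `[[`, numeric(1), "time")
}

# equilibration-discard contract: keep frames with time >= t_init
.analysis_frames <- function(traj, t_init = 0) {
  keep <- frame_times(traj) >= t_init
  if (!any(keep))
    stop("no frames left after discarding t < ", t_init, " ps")
  traj$frames[keep]
}

# unwrap a chain's coordinates across periodic images, walking the backbone
.unwrap_chain <- function(pos, geometry) {
  if (geometry$kind != "box" || nrow(pos) < 2) return(pos)
  L <- geometry$L
  d <- diff(pos)
  for (k in 1:3) d[, k] <- .min_image(d[, k], L[k])
  cs <- apply(d, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  rbind(pos[1, , drop = FALSE], sweep(cs, 2, pos[1, ], "+"))
}
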