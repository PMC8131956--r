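# Solvent-accessible surface area (Shrake-Rupley), APR exposure change
# between conditions, and occluded-surface packing density.

#' Shrake-Rupley SASA parameters
#'
#' @param probe probe (water) radius in Angstrom, default 1.4.
#' @param dots test points per atom sphere (default 960, minimum 60); the
#'   dot error on an isolated sphere is about 2% at the default.
#' @return a `sasa_params` list; van der Waals radii are C 1.70, N 1.55,
#'   O 1.52, S 1.80 Angstrom (unknown elements get the carbon radius with a
#'   warning), hydrogens never contribute.
#' @export
sasa_params <- function(probe = 1.4, dots = 960L) {
  if (probe < 0) stopf("probe radius must be >= 0")
  if (dots < 60) stopf("need at least 60 dots per atom")
  structure(list(probe = probe, dots = as.integer(dots)),
            class = "sasa_params")
}

#' Occluded-surface packing parameters
#'
#' @param rl_max maximum ray length in Angstrom (default 2.8, one water
#'   diameter).
#' @param dots rays per atom sphere (default 960).
#' @return an `osp_params` list.
#' @export
osp_params <- function(rl_max = 2.8, dots = 960L) {
  if (rl_max <= 0) stopf("rl_max must be > 0")
  if (dots < 60) stopf("need at least 60 dots per atom")
  structure(list(rl_max = rl_max, dots = as.integer(dots)),
            class = "osp_params")
}

#' Per-residue solvent-accessible surface area of one frame
#'
#' Shrake-Rupley: each atom's accessible area is the fraction of
#' quasi-uniform test points on its expanded sphere (vdW + probe radius)
#' that fall inside no neighbour's expanded sphere, times the expanded
#' sphere area.  Residue values are sums over the residue's atoms.
#'
#' @param frame coordinates for the full topology (default: the
#'   structure's own).
#' @param structure a `fab_structure`.
#' @param params a `sasa_params`.
#' @return named numeric vector of areas in Angstrom^2 (names = residue
#'   numbers).
#' @export
residue_sasa <- function(structure, frame = NULL, params = sasa_params()) {
  xyz <- if (is.null(frame)) get_coords(structure) else get_coords(frame)
  if (nrow(xyz) == 0L) stopf("structure has no atoms")
  radii <- vdw_radii(structure$atoms$element) + params$probe
  per_atom <- .cpp_sasa(xyz, radii, params$dots)
  out <- tapply(per_atom, structure$atoms$resno, sum)
  setNames(as.numeric(out), names(out))
}

# time-mean summed SASA of each APR for one trajectory
.apr_traj_sasa <- function(traj, aprs, params, stride = 1L) {
  frames <- seq(1L, n_frames(traj), by = stride)
  resno <- traj$topology$atoms$resno
  max_res <- max(resno)
  for (nm in names(aprs))
    if (aprs[[nm]][2] > max_res)
      stopf("APR %s extends beyond the structure (last residue %d)", nm, max_res)
  acc <- setNames(numeric(length(aprs)), names(aprs))
  for (f in frames) {
    rs <- residue_sasa(traj$topology, traj$coords[, , f], params)
    rn <- as.integer(names(rs))
    for (nm in names(aprs)) {
      iv <- aprs[[nm]]
      acc[nm] <- acc[nm] + sum(rs[rn >= iv[1] & rn <= iv[2]])
    }
  }
  acc / length(frames)
}

#' APR solvent-exposure change between conditions
#'
#' For each replicate pairing, the time-mean summed SASA of every
#' aggregation-prone region is computed for the stress and the reference
#' trajectories; the change is 100 x (mean_stress - mean_ref) / mean_ref,
#' with mean and SEM over replicate pairings (reference-condition values
#' serve as the benchmark).
#'
#' @param stress,reference lists of `fab_trajectory` (paired by index).
#' @param aprs an `apr_set`.
#' @param params a `sasa_params`.
#' @param stride evaluate every `stride`-th frame (time-mean subsampling).
#' @return data.frame with columns apr, sasa_ref, sasa_stress (replicate
#'   means, Angstrom^2), change (%), sem, n.
#' @export
apr_sasa_change <- function(stress, reference, aprs, params = sasa_params(),
                            stride = 1L) {
  if (length(stress) != length(reference))
    stopf("stress and reference must have the same number of replicates")
  n_rep <- length(stress)
  s <- sapply(stress, .apr_traj_sasa, aprs = aprs, params = params, stride = stride)
  r <- sapply(reference, .apr_traj_sasa, aprs = aprs, params = params, stride = stride)
  s <- matrix(s, ncol = n_rep); r <- matrix(r, ncol = n_rep)
  change <- 100 * (s - r) / r
  data.frame(apr = names(aprs),
             sasa_ref = rowMeans(r), sasa_stress = rowMeans(s),
             change = rowMeans(change),
             sem = if (n_rep > 1) apply(change, 1, sd) / sqrt(n_rep) else 0,
             n = n_rep, row.names = NULL, stringsAsFactors = FALSE)
}

#' Occluded-surface packing density per residue
#'
#' For every test point on an atom's van der Waals sphere the outward
#' normal ray is cast; if it intersects a neighbouring vdW sphere within
#' the maximum ray length RL_max the point contributes weight
#' (1 - RL/RL_max).  The atom value is the mean point weight, always in
#' 0 to 1: 0 for a completely exposed atom, approaching 1 when the whole
#' surface is in van der Waals contact.  Residue values are
#' vdW-area-weighted means over the residue's atoms.  Rays start on the
#' vdW sphere (not the molecular surface), so absolute values are
#' comparable within this implementation only.
#'
#' @param structure a `fab_structure`.
#' @param frame coordinates (default: the structure's own).
#' @param params an `osp_params`.
#' @return named numeric vector of OSP values in the unit interval per residue.
#' @export
occluded_surface_packing <- function(structure, frame = NULL,
                                     params = osp_params()) {
  xyz <- if (is.null(frame)) get_coords(structure) else get_coords(frame)
  if (nrow(xyz) == 0L) stopf("structure has no atoms")
  radii <- vdw_radii(structure$atoms$element)
  per_atom <- .cpp_osp(xyz, radii, params$rl_max, params$dots)
  w <- 4 * pi * radii^2
  resno <- structure$atoms$resno
  num <- tapply(per_atom * w, resno, sum)
  den <- tapply(w, resno, sum)
  setNames(as.numeric(num / den), names(num))
}
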