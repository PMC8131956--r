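# Rigid-body superposition and deformation metrics: RMSD, windowed RMSF,
# radius of gyration, replicate aggregation.  All metrics operate on heavy
# atoms ("all-atom" here means all heavy atoms, side chains included).

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two coordinate sets, via SVD of the covariance
#' matrix with the usual sign correction so the rotation has determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @param weights optional per-atom weights (default uniform).
#' @return list with `rotation` (3 x 3), `translation` (length 3, such that
#'   `fitted = mobile %*% rotation + translation`), `rmsd` (Angstrom) and
#'   `fitted` coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- get_coords(mobile); reference <- get_coords(reference)
  if (nrow(mobile) != nrow(reference))
    stopf("coordinate sets differ in size: %d vs %d atoms",
          nrow(mobile), nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stopf("superposition needs at least 3 atoms, got %d", n)
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) == 0)
    stopf("weights must be %d non-negative values with positive sum", n)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  pm <- sweep(mobile, 2, cm)
  pr <- sweep(reference, 2, cr)
  h <- crossprod(pm * w, pr)          # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rotation <- t(rot)                  # row-vector convention
  fitted <- pm %*% rotation
  rmsd <- sqrt(sum(w * rowSums((fitted - pr)^2)))
  translation <- cr - cm %*% rotation
  list(rotation = rotation, translation = as.numeric(translation),
       rmsd = rmsd, fitted = sweep(fitted, 2, cr, "+"))
}

# rmsd between already-aligned coordinate sets (no fitting)
raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of a region after fitting on that region
#'
#' Each frame is superposed onto the reference using only the region's heavy
#' atoms, then the all-heavy-atom RMSD over that same region is reported
#' ("individual domains with the corresponding domain as the reference").
#'
#' @param traj a `fab_trajectory`.
#' @param reference a `fab_structure` sharing the trajectory's atom order.
#' @param region domain name in `map` (or "all" for the whole protein).
#' @param map a `domain_map`.
#' @param replicate replicate identifier stored in the output.
#' @return data.frame (class `rmsd_series`) with columns region, replicate,
#'   time_ns, value.
#' @export
domain_rmsd_series <- function(traj, reference, region, map,
                               replicate = 1L) {
  idx <- if (identical(region, "all")) seq_len(nrow(traj$topology$atoms))
         else select_region(traj, map, region)
  if (is.list(idx)) idx <- unlist(idx)
  if (length(idx) == 0L) stopf("region %s selects no atoms", region)
  ref <- get_coords(reference)[idx, , drop = FALSE]
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    kabsch_superpose(traj$coords[idx, , f], ref)$rmsd
  }, 1.0)
  out <- data.frame(region = region, replicate = replicate,
                    time_ns = frame_times(traj), value = vals,
                    stringsAsFactors = FALSE)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Windowed per-residue RMSF of a region
#'
#' Frames are partitioned into consecutive non-overlapping time windows (a
#' frame landing exactly on a boundary joins the preceding window).  Within
#' each window every frame is fitted to the static reference on the region's
#' atoms, fluctuations are taken about the window-mean coordinates, and
#' per-residue values are the mean over each residue's atoms.  Fitting per
#' domain before the fluctuation calculation removes inter-domain motion
#' from the residue-level signal.
#'
#' @inheritParams domain_rmsd_series
#' @param window_ns window span in ns (default 10); must cover at least two
#'   frames.
#' @param reference fit target (default: the trajectory topology).
#' @return data.frame (class `rmsf_profile`) with columns region, window,
#'   t_start_ns, t_end_ns, resno, rmsf.
#' @export
windowed_rmsf <- function(traj, region, map, window_ns = 10,
                          reference = NULL, replicate = 1L) {
  if (window_ns < 2 * traj$frame_interval_ns)
    stopf("window_ns must cover at least two frames (>= %g ns)",
          2 * traj$frame_interval_ns)
  idx <- if (identical(region, "all")) seq_len(nrow(traj$topology$atoms))
         else select_region(traj, map, region)
  if (is.list(idx)) idx <- unlist(idx)
  if (length(idx) == 0L) stopf("region %s selects no atoms", region)
  reference <- reference %||% traj$topology
  ref <- get_coords(reference)[idx, , drop = FALSE]
  times <- frame_times(traj)
  win <- pmax(1L, ceiling(times / window_ns - 1e-9))
  resno <- traj$topology$atoms$resno[idx]
  out <- vector("list", max(win))
  for (k in seq_len(max(win))) {
    frames <- which(win == k)
    if (length(frames) < 2L) next
    fitted <- array(NA_real_, dim = c(length(idx), 3L, length(frames)))
    for (i in seq_along(frames))
      fitted[, , i] <- kabsch_superpose(traj$coords[idx, , frames[i]], ref)$fitted
    mu <- apply(fitted, c(1, 2), mean)
    dev2 <- sweep(fitted, c(1, 2), mu)^2
    atom_rmsf <- sqrt(apply(dev2, 1, sum) / length(frames))
    res_rmsf <- tapply(atom_rmsf, resno, mean)
    out[[k]] <- data.frame(region = region, replicate = replicate,
                           window = k,
                           t_start_ns = min(times[frames]),
                           t_end_ns = max(times[frames]),
                           resno = as.integer(names(res_rmsf)),
                           rmsf = as.numeric(res_rmsf),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the atoms from their centre
#' of mass.
#'
#' @param frame coordinates (n x 3 matrix, or a `fab_structure`).
#' @param masses per-atom masses; default from the element mass table when
#'   `frame` is a structure, else uniform.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  if (inherits(frame, "fab_structure") && is.null(masses))
    masses <- element_masses(frame$atoms$element)
  xyz <- get_coords(frame)
  masses <- masses %||% rep(1, nrow(xyz))
  if (any(masses <= 0) || sum(masses) == 0) stopf("masses must be positive")
  com <- colSums(xyz * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(xyz, 2, com)^2)) / sum(masses))
}

#' Aggregate per-replicate series into mean and SEM
#'
#' All series must share their time axis and region.  SEM uses the sample
#' standard deviation (n - 1 denominator) over replicates.
#'
#' @param series_list list of data.frames with columns time_ns and value
#'   (e.g. `rmsd_series` or `q_series` objects for one region).
#' @return data.frame with columns region, time_ns, mean, sem, n.
#' @export
aggregate_replicates <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  t0 <- series_list[[1]]$time_ns
  for (s in series_list[-1])
    if (length(s$time_ns) != length(t0) || any(abs(s$time_ns - t0) > 1e-9))
      stopf("replicate series have mismatched time axes")
  region <- if ("region" %in% names(series_list[[1]])) series_list[[1]]$region[1] else NA
  valcol <- intersect(c("value", "q"), names(series_list[[1]]))[1]
  stats <- replicate_stats(lapply(series_list, `[[`, valcol))
  cbind(data.frame(region = region, time_ns = t0, stringsAsFactors = FALSE), stats)
}
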