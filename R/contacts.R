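# Native-contact extraction and soft-cutoff contact fractions.
#
# A native contact is a heavy-atom pair within ref_radius in the reference
# structure.  Its "formed" status in a frame is scored with the logistic
# soft cutoff
#     q_ij = 1 / (1 + exp(beta * (r_ij - lam * r0_ij)))
# and the region fraction Q is the mean over pairs, so a hard threshold at
# the native distance is avoided.

#' Soft-cutoff contact parameters
#'
#' Defaults are the standard soft-cutoff constants of the cited contact
#' analysis framework: beta = 5 / Angstrom, lambda = 1.8, reference radius
#' 4.5 Angstrom (heavy atoms), with intra-region pairs closer than 3
#' residues in sequence excluded.  All four are configurable.
#'
#' @param beta logistic steepness in 1/Angstrom (> 0).
#' @param lam dimensionless tolerance scale on the native distance (>= 1).
#' @param ref_radius native-contact distance cutoff in Angstrom (> 0).
#' @param min_seq_sep minimum residue separation for intra-domain pairs
#'   (interfaces ignore sequence separation).
#' @return a `contact_params` list.
#' @export
contact_params <- function(beta = 5.0, lam = 1.8, ref_radius = 4.5,
                           min_seq_sep = 3L) {
  if (beta <= 0) stopf("beta must be > 0")
  if (lam < 1) stopf("lam must be >= 1")
  if (ref_radius <= 0) stopf("ref_radius must be > 0")
  structure(list(beta = beta, lam = lam, ref_radius = ref_radius,
                 min_seq_sep = as.integer(min_seq_sep)),
            class = "contact_params")
}

#' Reference (native) contacts of a region
#'
#' All heavy-atom pairs within `ref_radius` in the reference structure.
#' For a domain, pairs with residue separation below `min_seq_sep` are
#' excluded (trivially bonded neighbours); for an interface, all
#' cross-domain pairs are kept regardless of sequence separation.
#'
#' @param reference a `fab_structure`.
#' @param region domain or interface name.
#' @param map a `domain_map`.
#' @param params a `contact_params`.
#' @return a `contact_set`: list with `region`, `pairs` (data.frame i, j,
#'   r0, resno_i, resno_j) and `params`.
#' @export
build_reference_contacts <- function(reference, region, map,
                                     params = contact_params()) {
  xyz <- get_coords(reference)
  resno <- reference$atoms$resno
  sel <- select_region(reference, map, region)
  if (is.list(sel)) {                  # interface: cross-domain pairs
    ia <- sel[[1]]; ib <- sel[[2]]
    if (length(ia) == 0L || length(ib) == 0L)
      stopf("interface %s has an empty side", region)
    d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    hit <- which(d2 <= params$ref_radius^2, arr.ind = TRUE)
    i <- ia[hit[, 1]]; j <- ib[hit[, 2]]
  } else {
    if (length(sel) == 0L) stopf("region %s selects no atoms", region)
    d2 <- cross_dist2(xyz[sel, , drop = FALSE], xyz[sel, , drop = FALSE])
    hit <- which(upper.tri(d2) & d2 <= params$ref_radius^2, arr.ind = TRUE)
    i <- sel[hit[, 1]]; j <- sel[hit[, 2]]
    keep <- abs(resno[i] - resno[j]) >= params$min_seq_sep
    i <- i[keep]; j <- j[keep]
  }
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  r0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  pairs <- data.frame(i = i, j = j, r0 = r0,
                      resno_i = resno[i], resno_j = resno[j])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(region = region, pairs = pairs, params = params),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set '%s': %d native pairs (r0 <= %.2f A)\n",
              x$region, nrow(x$pairs), x$params$ref_radius))
  invisible(x)
}

.pair_dist <- function(xyz, pairs) {
  sqrt(rowSums((xyz[pairs$i, , drop = FALSE] - xyz[pairs$j, , drop = FALSE])^2))
}

.soft_scores <- function(r, r0, params) {
  1 / (1 + exp(params$beta * (r - params$lam * r0)))
}

#' Soft-cutoff native-contact fraction of one frame
#'
#' @param frame coordinates for the full topology (n x 3).
#' @param contacts a `contact_set`.
#' @param params contact parameters (default: those stored in `contacts`).
#' @return the fraction Q in (0, 1).
#' @export
soft_cut_fraction <- function(frame, contacts, params = NULL) {
  params <- params %||% contacts$params
  if (nrow(contacts$pairs) == 0L)
    stopf("contact set '%s' is empty: fraction undefined", contacts$region)
  frame <- get_coords(frame)
  if (max(contacts$pairs$j) > nrow(frame))
    stopf("contact atom index %d exceeds frame size %d",
          max(contacts$pairs$j), nrow(frame))
  r <- .pair_dist(frame, contacts$pairs)
  mean(.soft_scores(r, contacts$pairs$r0, params))
}

#' Native-contact fraction along a trajectory
#'
#' @param traj a `fab_trajectory`.
#' @param contacts a `contact_set` built on the matching reference.
#' @inheritParams soft_cut_fraction
#' @param replicate replicate identifier stored in the output.
#' @return data.frame (class `q_series`) with columns region, replicate,
#'   time_ns, q.
#' @export
contact_series <- function(traj, contacts, params = NULL, replicate = 1L) {
  params <- params %||% contacts$params
  if (nrow(contacts$pairs) == 0L)
    stopf("contact set '%s' is empty", contacts$region)
  if (max(contacts$pairs$j) > dim(traj$coords)[1])
    stopf("contact atom index %d exceeds topology size %d",
          max(contacts$pairs$j), dim(traj$coords)[1])
  q <- vapply(seq_len(n_frames(traj)), function(f) {
    r <- .pair_dist(traj$coords[, , f], contacts$pairs)
    mean(.soft_scores(r, contacts$pairs$r0, params))
  }, 1.0)
  out <- data.frame(region = contacts$region, replicate = replicate,
                    time_ns = frame_times(traj), q = q,
                    stringsAsFactors = FALSE)
  class(out) <- c("q_series", "data.frame")
  out
}

#' Residue-level native-contact fractions of one frame
#'
#' For each residue appearing in the contact set, the mean soft-cutoff
#' score over all pairs that involve it.  Residues with no pairs are absent
#' from the result.
#'
#' @inheritParams soft_cut_fraction
#' @return named numeric vector (names = residue numbers).
#' @export
residue_fraction <- function(frame, contacts, params = NULL) {
  params <- params %||% contacts$params
  if (nrow(contacts$pairs) == 0L)
    stopf("contact set '%s' is empty", contacts$region)
  frame <- get_coords(frame)
  r <- .pair_dist(frame, contacts$pairs)
  s <- .soft_scores(r, contacts$pairs$r0, params)
  res <- c(contacts$pairs$resno_i, contacts$pairs$resno_j)
  sc <- c(s, s)
  out <- tapply(sc, res, mean)
  setNames(as.numeric(out), names(out))
}

#' Total contacts (native and non-native) between two atom sets
#'
#' Number of cross-set heavy-atom pairs within `cutoff` in the given frame.
#'
#' @param frame coordinates (n x 3).
#' @param set_a,set_b disjoint atom index vectors.
#' @param cutoff distance cutoff in Angstrom (default 6.0).
#' @return integer pair count.
#' @export
count_total_contacts <- function(frame, set_a, set_b, cutoff = 6.0) {
  if (length(intersect(set_a, set_b)) > 0L)
    stopf("atom sets overlap: total contacts are defined between disjoint sets")
  frame <- get_coords(frame)
  d2 <- cross_dist2(frame[set_a, , drop = FALSE], frame[set_b, , drop = FALSE])
  sum(d2 <= cutoff^2)
}
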