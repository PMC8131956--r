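# shared fixtures: all built in code, cached per session where expensive

# a fixed-width PDB ATOM line (v3.3 columns)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element = substr(name, 1, 1), altloc = " ",
                          icode = " ", b = 0) {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f  1.00%6.2f          %2s",
          serial, name, altloc, resname, chain, resno, icode, x, y, z, b, element)
}

# minimal structure straight from an atom table (bypasses PDB text)
mk_structure <- function(name, element, resno, xyz, resname = "ALA",
                         chain = "A") {
  atoms <- data.frame(serial = seq_along(name), name = name,
                      element = element, resno = resno,
                      resname = rep_len(resname, length(name)),
                      chain = rep_len(chain, length(name)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  stressmap:::new_fab_structure(atoms)
}

# trajectory from a topology and a list of coordinate matrices
mk_traj <- function(topology, frames, dt = 0.1) {
  coords <- array(NA_real_, dim = c(nrow(topology$atoms), 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  stressmap:::new_fab_trajectory(topology, coords, dt)
}

# expensive shared fixtures, built once per test session
.fixture_env <- new.env(parent = emptyenv())

toy_fab_cached <- function() {
  if (is.null(.fixture_env$fab)) .fixture_env$fab <- build_toy_fab()
  .fixture_env$fab
}

# a paired antiparallel hairpin (two 10-residue strands, resno 1-10 and
# 15-24) cut out of the cached toy fab's VL domain
hairpin_cached <- function() {
  if (is.null(.fixture_env$hairpin)) {
    fab <- toy_fab_cached()
    at <- fab$structure$atoms
    keep <- at$resno %in% c(1:10, 15:24) & at$name %in% c("N", "CA", "C", "O")
    .fixture_env$hairpin <- stressmap:::new_fab_structure(at[keep, ])
  }
  .fixture_env$hairpin
}

# random rigid transform (rotation + translation) under the current seed
random_rigid <- function(xyz) {
  th <- stats::runif(3, -pi, pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  sweep(xyz %*% (rx %*% ry %*% rz), 2, stats::runif(3, -20, 20), "+")
}

# independent brute-force oracle for the optimal-fit RMSD: hierarchical
# Euler-angle grid search (translation handled by centroid alignment)
grid_search_rmsd <- function(mobile, reference, coarse = 10, fine = 1) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm); pr <- sweep(reference, 2, cr)
  rot <- function(a, b, g) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cg <- cos(g); sg <- sin(g)
    rz1 <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
    ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
    rz2 <- rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
    rz1 %*% ry %*% rz2
  }
  eval_r <- function(a, b, g) {
    sqrt(mean(rowSums((pm %*% rot(a, b, g) - pr)^2)))
  }
  best <- c(0, 0, 0); best_v <- Inf
  step <- coarse * pi / 180
  for (a in seq(-pi, pi, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(-pi, pi, by = step)) {
        v <- eval_r(a, b, g)
        if (v < best_v) { best_v <- v; best <- c(a, b, g) }
      }
  fstep <- fine * pi / 180
  for (a in seq(best[1] - step, best[1] + step, by = fstep))
    for (b in seq(best[2] - step, best[2] + step, by = fstep))
      for (g in seq(best[3] - step, best[3] + step, by = fstep)) {
        v <- eval_r(a, b, g)
        if (v < best_v) { best_v <- v; best <- c(a, b, g) }
      }
  best_v
}
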