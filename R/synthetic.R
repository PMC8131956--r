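# Synthetic mini-Fab generator: an idealised four-domain structure (two
# chains, two inter-chain interfaces, designed salt bridges, buried
# "aggregation-prone" loops) and stress trajectories with known ground
# truth.  The generator emulates the statistical structure of three
# condition classes: a stationary reference, a "low-pH-like" condition
# that selectively deforms one constant-region domain and eliminates its
# glutamate salt bridges, and a "high-temperature-like" condition with
# larger global fluctuations plus progressive separation of both
# inter-chain interfaces.  Motion is i.i.d. Gaussian jitter plus scheduled
# deterministic displacements -- sufficient for validating the metrics, with
# no claim of physical realism.

.bond_geom <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                   b_c_o = 1.231, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                   a_c_n_ca = 121.7, a_ca_c_o = 120.8)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# place atom D given A-B-C with bond |CD|, angle B-C-D, torsion A-B-C-D
.place_atom <- function(a, b, c3, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit3(c3 - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * cos(tor) * sin(ang), bond * sin(tor) * sin(ang))
  c3 + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal polypeptide backbone from internal coordinates
#'
#' Sequential construction of backbone N, CA, C, O with standard bond
#' geometry (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom) and
#' per-residue phi/psi/omega dihedrals (defaults are ideal antiparallel
#' beta-strand values phi = -139, psi = +135, trans peptide).
#'
#' @param n_residues number of residues (>= 2).
#' @param phi,psi,omega backbone dihedrals in degrees (recycled).
#' @param chain chain identifier.
#' @param start_resno first residue number.
#' @param resnames residue names (recycled).
#' @return a `fab_structure` with 4 atoms per residue.
#' @export
build_backbone <- function(n_residues, phi = -139, psi = 135, omega = 180,
                           chain = "A", start_resno = 1L, resnames = "ALA") {
  if (n_residues < 2) stopf("need at least 2 residues")
  if (!all(is.finite(c(phi, psi, omega)))) stopf("non-finite dihedral")
  phi <- rep_len(phi, n_residues)
  psi <- rep_len(psi, n_residues)
  omega <- rep_len(omega, n_residues)
  resnames <- rep_len(resnames, n_residues)
  g <- .bond_geom
  nc <- matrix(NA_real_, n_residues * 3, 3)  # N, CA, C per residue
  o <- matrix(NA_real_, n_residues, 3)
  nc[1, ] <- c(0, 0, 0)
  nc[2, ] <- c(g$b_n_ca, 0, 0)
  a3 <- (180 - g$a_n_ca_c) * pi / 180   # angle N-CA-C seeded in the xy plane
  nc[3, ] <- nc[2, ] + g$b_ca_c * c(cos(a3), sin(a3), 0)
  for (i in seq_len(n_residues)) {
    ni <- (i - 1) * 3 + 1
    if (i > 1) {
      # N_i from (N_{i-1}, CA_{i-1}, C_{i-1}) with torsion psi_{i-1}
      nc[ni, ] <- .place_atom(nc[ni - 3, ], nc[ni - 2, ], nc[ni - 1, ],
                              g$b_c_n, g$a_ca_c_n, psi[i - 1])
      # CA_i from (CA_{i-1}, C_{i-1}, N_i) with torsion omega
      nc[ni + 1, ] <- .place_atom(nc[ni - 2, ], nc[ni - 1, ], nc[ni, ],
                                  g$b_n_ca, g$a_c_n_ca, omega[i - 1])
      # C_i from (C_{i-1}, N_i, CA_i) with torsion phi_i
      nc[ni + 2, ] <- .place_atom(nc[ni - 1, ], nc[ni, ], nc[ni + 1, ],
                                  g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    # O_i from (N_i, CA_i, C_i) with torsion psi_i - 180
    o[i, ] <- .place_atom(nc[ni, ], nc[ni + 1, ], nc[ni + 2, ],
                          g$b_c_o, g$a_ca_c_o, psi[i] - 180)
  }
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    ni <- (i - 1) * 3 + 1
    data.frame(serial = 0L,
               name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               resno = start_resno + i - 1L,
               resname = resnames[i], chain = chain,
               x = c(nc[ni:(ni + 2), 1], o[i, 1]),
               y = c(nc[ni:(ni + 2), 2], o[i, 2]),
               z = c(nc[ni:(ni + 2), 3], o[i, 3]),
               stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  new_fab_structure(atoms, title = "ideal backbone")
}

# rotate/translate a structure so CA(first) is at the origin and
# CA(last) lies along +x; deterministic auxiliary axes
.canonicalise_strand <- function(s) {
  xyz <- get_coords(s)
  ca <- xyz[s$atoms$name == "CA", , drop = FALSE]
  x_ax <- unit3(ca[nrow(ca), ] - ca[1, ])
  ref <- if (abs(x_ax[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  y_ax <- unit3(cross3(ref, x_ax))
  z_ax <- cross3(x_ax, y_ax)
  rot <- rbind(x_ax, y_ax, z_ax)
  new_xyz <- sweep(xyz, 2, ca[1, ]) %*% t(rot)
  s$atoms$x <- new_xyz[, 1]; s$atoms$y <- new_xyz[, 2]; s$atoms$z <- new_xyz[, 3]
  s
}

.apply_xyz <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# offset cache for the antiparallel pairing search
.pair_cache <- new.env(parent = emptyenv())

# find the rigid offset (dx, dy, dz) that maximises inter-strand
# Kabsch-Sander hydrogen bonds between a strand and its 180-degree-rotated
# copy near the requested separation; deterministic two-stage grid search
# over vectorised bond energies
.antiparallel_offset <- function(strand, separation) {
  key <- sprintf("%d_%.3f", sum(strand$atoms$name == "CA"), separation)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  at <- strand$atoms
  xyz1 <- get_coords(strand)
  pick <- function(nm) xyz1[at$name == nm, , drop = FALSE]
  n1 <- pick("N"); ca1 <- pick("CA"); c1 <- pick("C"); o1 <- pick("O")
  n_res <- nrow(ca1)
  # amide H on residues 2..n from the previous residue's C=O
  h1 <- matrix(NA_real_, n_res, 3)
  for (i in 2:n_res) {
    u <- unit3(c1[i - 1, ] - o1[i - 1, ])
    h1[i, ] <- n1[i, ] + u
  }
  flip <- diag(c(-1, 1, -1))            # 180 degrees about the y axis
  lx <- max(ca1[, 1])
  kpar <- hbond_params()
  score_at <- function(off) {
    tr <- function(m) sweep(m %*% flip, 2, off, "+")
    n2 <- tr(n1); c2 <- tr(c1); o2 <- tr(o1); ca2 <- tr(ca1)
    h2 <- tr(h1)
    all2 <- tr(xyz1)
    if (min(cross_dist2(xyz1, all2)) < 2.4^2) return(-1)     # clash
    if (min(cross_dist2(ca1, ca2)) < 4.2^2) return(-1)       # interdigitated
    nb <- function(nd, hd, cacc, oacc) {  # donor-strand -> acceptor-strand
      r_on <- sqrt(cross_dist2(nd, oacc)); r_ch <- sqrt(cross_dist2(hd, cacc))
      r_oh <- sqrt(cross_dist2(hd, oacc)); r_cn <- sqrt(cross_dist2(nd, cacc))
      e <- kpar$coupling * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      e[is.na(e)] <- 0
      sum(e < kpar$cutoff)
    }
    nb(n1, h1, c2, o2) + nb(n2, h2, c1, o1)
  }
  best <- NULL; best_score <- -Inf
  for (dx in seq(lx - 4, lx + 4, by = 0.3))
    for (dy in seq(-0.8, 1.2, by = 0.25))
      for (dz in seq(-2, 2, by = 0.25)) {
        sc <- score_at(c(dx, separation + dy, dz))
        if (sc > best_score) { best_score <- sc; best <- c(dx, separation + dy, dz) }
      }
  for (dx in seq(best[1] - 0.3, best[1] + 0.3, by = 0.05))
    for (dy in seq(best[2] - 0.25, best[2] + 0.25, by = 0.05))
      for (dz in seq(best[3] - 0.25, best[3] + 0.25, by = 0.05)) {
        sc <- score_at(c(dx, dy, dz))
        if (sc > best_score) { best_score <- sc; best <- c(dx, dy, dz) }
      }
  res <- list(offset = best, n_bonds = best_score)
  .pair_cache[[key]] <- res
  res
}

#' Specification of the synthetic mini-Fab
#'
#' Four hairpin domains (two strands of `n_strand` residues joined by an
#' `n_turn`-residue loop) arranged as a light chain (VL, CL) and a heavy
#' chain (VH, CH1) with VL-VH and CL-CH1 interfaces.  Each domain's loop is
#' a designated "APR" buried inside a shell of occluder pseudo-atoms;
#' designed salt bridges carry per-condition occupancy schedules (fractions
#' of frames in which each bridge is formed).  The low-pH-like schedule
#' eliminates every glutamate bridge; the high-temperature-like schedule
#' halves all occupancies.
#'
#' @param n_strand residues per strand (default 10).
#' @param n_turn residues per loop (default 4).
#' @param separation strand separation in the hairpin, Angstrom.
#' @param sheet_gap distance between the light- and heavy-chain sheet
#'   planes, Angstrom.
#' @param phi,psi strand dihedrals in degrees.
#' @return a `toy_fab_spec` list (includes the default occupancy
#'   schedules).
#' @export
toy_fab_spec <- function(n_strand = 10L, n_turn = 4L, separation = 4.9,
                         sheet_gap = 7.0, phi = -139, psi = 145) {
  n_dom <- n_strand * 2L + n_turn
  off <- c(VL = 0L, CL = n_dom, VH = 2L * n_dom, CH1 = 3L * n_dom)
  l <- function(dom, loc) off[[dom]] + loc
  bridges <- data.frame(
    acid_resno = c(l("VL", 4), l("CL", 3), l("CL", 5), l("CL", 7), l("CL", 9),
                   l("CH1", 5), l("CH1", 8), l("CL", 6)),
    acid_resname = c("ASP", "GLU", "GLU", "ASP", "GLU", "GLU", "ASP", "GLU"),
    base_resno = c(l("VL", 21), l("CL", 22), l("CL", 20), l("CL", 18),
                   l("CL", 16), l("CH1", 20), l("CH1", 17), l("CH1", 6)),
    base_resname = c("LYS", "LYS", "LYS", "LYS", "ARG", "LYS", "ARG", "LYS"),
    stringsAsFactors = FALSE)
  reference <- c(0.45, 0.9, 0.7, 0.6, 0.5, 0.55, 0.35, 0.3)
  low_ph <- ifelse(bridges$acid_resname == "GLU", 0, reference)
  schedules <- list(reference = reference, low_ph_like = low_ph,
                    high_temp_like = reference * 0.5)
  structure(list(n_strand = as.integer(n_strand), n_turn = as.integer(n_turn),
                 separation = separation, sheet_gap = sheet_gap,
                 phi = phi, psi = psi, n_per_domain = n_dom,
                 domain_offsets = off, bridges = bridges,
                 schedules = schedules,
                 d_on = 3.0, d_off = 4.6,
                 cage_radius = 4.8, cage_dots = 14L),
            class = "toy_fab_spec")
}

# golden-spiral points on a unit sphere (R mirror of the C++ lattice)
.sphere_dots_r <- function(n) {
  k <- seq_len(n) - 1
  z <- 1 - 2 * (k + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * k
  cbind(r * cos(th), r * sin(th), z)
}

#' Build the synthetic mini-Fab structure
#'
#' Assembles four hairpin domains with interface pseudo side-chain atoms
#' (CB) facing the partner chain, occluder shells around each domain's
#' buried loop, and designed salt-bridge atoms (acidic OE/OD and basic
#' NZ/NE/NH placed at their "formed" geometry).  The returned bundle
#' carries the structure together with its region model and the designed
#' ground truth.
#'
#' @param spec a `toy_fab_spec`.
#' @return a `toy_fab`: list with `structure`, `map` (domain_map), `smap`
#'   (strand_map), `aprs` (apr_set), `spec`, `bridges` (placement table)
#'   and index groups used by the trajectory generator.
#' @export
build_toy_fab <- function(spec = toy_fab_spec()) {
  ns <- spec$n_strand; nt <- spec$n_turn; nd <- spec$n_per_domain
  strand <- .canonicalise_strand(build_backbone(ns, phi = spec$phi, psi = spec$psi))
  pair <- .antiparallel_offset(strand, spec$separation)
  xyz1 <- get_coords(strand)
  flip <- diag(c(-1, 1, -1))
  xyz2 <- sweep(xyz1 %*% flip, 2, pair$offset, "+")

  build_domain <- function(dom, offset_res, chain, shift, up) {
    res1 <- offset_res + seq_len(ns)
    res2 <- offset_res + ns + nt + seq_len(ns)
    turn <- offset_res + ns + seq_len(nt)
    mk <- function(xyz, resnos) {
      do.call(rbind, lapply(seq_along(resnos), function(i) {
        rows <- (i - 1) * 4 + 1:4
        data.frame(serial = 0L, name = c("N", "CA", "C", "O"),
                   element = c("N", "C", "C", "O"), resno = resnos[i],
                   resname = "ALA", chain = chain,
                   x = xyz[rows, 1], y = xyz[rows, 2], z = xyz[rows, 3],
                   stringsAsFactors = FALSE)
      }))
    }
    at <- rbind(mk(xyz1, res1), mk(xyz2, res2))
    # interface pseudo side chains on every strand residue, facing the
    # partner chain
    ca <- at[at$name == "CA", , drop = FALSE]
    cb <- ca
    cb$name <- "CB"; cb$element <- "C"
    cb$z <- cb$z + 1.8 * up
    at <- rbind(at, cb)
    # buried loop ("APR"): compact cluster just past the turn end of the
    # hairpin, midway between the strands and displaced away from the
    # partner chain so the two chains' occluder shells cannot touch
    lx <- max(xyz1[, 1])
    centre <- c(lx + 4.5, pair$offset[2] / 2, -2.2 * up)
    th <- seq(45, 315, by = 90) * pi / 180
    loop_at <- do.call(rbind, lapply(seq_len(nt), function(i) {
      ca_i <- centre + 2.0 * c(0, cos(th[i]), sin(th[i]))
      pos <- rbind(N = ca_i + c(-1.2, 0.5, 0), CA = ca_i,
                   C = ca_i + c(1.2, 0.5, 0),
                   O = ca_i + c(1.5, 1.6, 0),
                   CB = ca_i + 0.8 * unit3(centre - ca_i + c(1e-3, 0, 0)))
      data.frame(serial = 0L, name = rownames(pos),
                 element = c("N", "C", "C", "O", "C"),
                 resno = turn[i], resname = "VAL", chain = chain,
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 stringsAsFactors = FALSE)
    }))
    at <- rbind(at, loop_at)
    # occluder shell around the loop, attached to strand residues
    dots <- sweep(spec$cage_radius * .sphere_dots_r(spec$cage_dots), 2, centre, "+")
    existing <- cbind(at$x, at$y, at$z)
    keep <- apply(cross_dist2(dots, existing), 1, min) > 2.2^2
    dots <- dots[keep, , drop = FALSE]
    if (nrow(dots) > 0) {
      strand_ca <- ca[, c("x", "y", "z")]
      nearest <- apply(cross_dist2(dots, as.matrix(strand_ca)), 1, which.min)
      host <- ca$resno[nearest]
      cage_at <- data.frame(serial = 0L,
                            name = paste0("CQ", LETTERS[stats::ave(seq_len(nrow(dots)),
                                                                   host, FUN = seq_along)]),
                            element = "C", resno = host, resname = "ALA",
                            chain = chain, x = dots[, 1], y = dots[, 2],
                            z = dots[, 3], stringsAsFactors = FALSE)
      at <- rbind(at, cage_at)
    }
    at$x <- at$x + shift[1]; at$y <- at$y + shift[2]; at$z <- at$z + shift[3]
    at[order(at$resno), ]   # stable: keeps N, CA, C, O first within a residue
  }

  gap_x <- 45
  off <- spec$domain_offsets
  at <- rbind(
    build_domain("VL", off[["VL"]], "L", c(0, 0, 0), up = +1),
    build_domain("CL", off[["CL"]], "L", c(gap_x, 0, 0), up = +1),
    build_domain("VH", off[["VH"]], "H", c(0, 0, spec$sheet_gap), up = -1),
    build_domain("CH1", off[["CH1"]], "H", c(gap_x, 0, spec$sheet_gap), up = -1))

  # designed salt-bridge side-chain atoms
  br <- spec$bridges
  br$ref_n_idx <- rep(NA_integer_, nrow(br))
  br$o1_idx <- rep(NA_integer_, nrow(br))
  br$o2_idx <- rep(NA_integer_, nrow(br))
  placements <- list()
  get_ca <- function(resno) {
    row <- at[at$resno == resno & at$name == "CA", ]
    c(row$x, row$y, row$z)
  }
  extra <- list()
  for (b in seq_len(nrow(br))) {
    ca_a <- get_ca(br$acid_resno[b]); ca_b <- get_ca(br$base_resno[b])
    dir <- unit3(ca_a - ca_b)
    perp <- cross3(dir, c(0, 0, 1))
    if (sqrt(sum(perp^2)) < 0.1) perp <- cross3(dir, c(0, 1, 0))
    perp <- unit3(perp)
    ch_a <- at$chain[at$resno == br$acid_resno[b]][1]
    ch_b <- at$chain[at$resno == br$base_resno[b]][1]
    at$resname[at$resno == br$acid_resno[b]] <- br$acid_resname[b]
    at$resname[at$resno == br$base_resno[b]] <- br$base_resname[b]
    if (br$base_resname[b] == "LYS") {
      npos <- rbind(NZ = ca_b + 1.5 * dir)
    } else {
      npos <- rbind(NE = ca_b + 1.5 * dir,
                    NH1 = ca_b + 2.4 * dir + 0.6 * perp,
                    NH2 = ca_b + 2.4 * dir - 0.6 * perp)
    }
    ref_name <- if (br$base_resname[b] == "LYS") "NZ" else "NH1"
    ref_n <- npos[ref_name, ]
    u <- unit3(ca_a - ref_n)
    perp2 <- cross3(u, c(0, 0, 1))
    if (sqrt(sum(perp2^2)) < 0.1) perp2 <- cross3(u, c(0, 1, 0))
    perp2 <- unit3(perp2)
    o_names <- if (br$acid_resname[b] == "GLU") c("OE1", "OE2") else c("OD1", "OD2")
    o1 <- ref_n + spec$d_on * u
    o2 <- o1 + 0.9 * perp2
    extra[[b]] <- data.frame(
      serial = 0L, name = c(rownames(npos), o_names),
      element = c(rep("N", nrow(npos)), "O", "O"),
      resno = c(rep(br$base_resno[b], nrow(npos)), rep(br$acid_resno[b], 2)),
      resname = c(rep(br$base_resname[b], nrow(npos)), rep(br$acid_resname[b], 2)),
      chain = c(rep(ch_b, nrow(npos)), rep(ch_a, 2)),
      x = c(npos[, 1], o1[1], o2[1]), y = c(npos[, 2], o1[2], o2[2]),
      z = c(npos[, 3], o1[3], o2[3]), stringsAsFactors = FALSE)
    placements[[b]] <- list(u = u, perp2 = perp2, ref_name = ref_name,
                            o_names = o_names)
  }
  at <- rbind(at, do.call(rbind, extra))
  at <- at[order(match(at$chain, c("L", "H")), at$resno), ]
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  # designed-placement clash check
  d2 <- cross_dist2(cbind(at$x, at$y, at$z), cbind(at$x, at$y, at$z))
  diag(d2) <- Inf
  neighbour <- abs(outer(at$resno, at$resno, "-")) <= 1   # incl. peptide bonds
  d2[neighbour] <- Inf
  if (min(d2) < 1.5^2) {
    ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    stopf("designed placements clash: %s%d:%s and %s%d:%s are %.2f A apart",
          at$resname[ij[1]], at$resno[ij[1]], at$name[ij[1]],
          at$resname[ij[2]], at$resno[ij[2]], at$name[ij[2]], sqrt(min(d2)))
  }
  st <- new_fab_structure(at, title = "synthetic mini-Fab")

  for (b in seq_len(nrow(br))) {
    p <- placements[[b]]
    br$ref_n_idx[b] <- which(at$resno == br$base_resno[b] & at$name == p$ref_name)
    br$o1_idx[b] <- which(at$resno == br$acid_resno[b] & at$name == p$o_names[1])
    br$o2_idx[b] <- which(at$resno == br$acid_resno[b] & at$name == p$o_names[2])
  }
  br$ux <- vapply(placements, function(p) p$u[1], 1.0)
  br$uy <- vapply(placements, function(p) p$u[2], 1.0)
  br$uz <- vapply(placements, function(p) p$u[3], 1.0)
  br$px <- vapply(placements, function(p) p$perp2[1], 1.0)
  br$py <- vapply(placements, function(p) p$perp2[2], 1.0)
  br$pz <- vapply(placements, function(p) p$perp2[3], 1.0)

  nd_ <- nd
  dm <- domain_map(list(VL = c(1, nd_), CL = c(nd_ + 1, 2 * nd_),
                        VH = c(2 * nd_ + 1, 3 * nd_), CH1 = c(3 * nd_ + 1, 4 * nd_)),
                   list("VL-VH" = c("VL", "VH"), "CL-CH1" = c("CL", "CH1")))
  smap_iv <- list()
  aprs_iv <- list()
  for (dom in names(off)) {
    o <- off[[dom]]
    smap_iv[[paste0(dom, "_A")]] <- c(o + 1, o + ns)
    smap_iv[[paste0(dom, "_B")]] <- c(o + ns + nt + 1, o + nd_)
    aprs_iv[[paste0("APR_", dom)]] <- c(o + ns + 1, o + ns + nt)
  }
  structure(list(structure = st, map = dm,
                 smap = strand_map(smap_iv, dm),
                 aprs = apr_set(aprs_iv, max_residue = 4 * nd_),
                 spec = spec, bridges = br,
                 groups = list(
                   heavy_idx = which(at$chain == "H"),
                   loop_idx = lapply(setNames(names(off), names(off)), function(dom)
                     residues_to_atoms(st, seq(off[[dom]] + ns + 1, off[[dom]] + ns + nt))),
                   bridge_idx = unique(c(br$ref_n_idx, br$o1_idx, br$o2_idx,
                                         unlist(lapply(seq_len(nrow(br)), function(b)
                                           which(at$resno == br$base_resno[b] &
                                                   at$name %in% c("NZ", "NE", "NH1", "NH2")))))))),
            class = "toy_fab")
}

#' Stress profile for the synthetic trajectory generator
#'
#' @param mode "reference" (stationary jitter), "low_ph_like" (jitter plus
#'   a ramped displacement of the target domain's buried loop and
#'   elimination of the glutamate salt bridges) or "high_temp_like"
#'   (larger global jitter plus a progressive rigid separation of the
#'   heavy chain from the light chain, opening both interfaces).
#' @param sigma per-atom Gaussian jitter in Angstrom (defaults: 0.25 for
#'   reference and low-pH-like, 0.6 for high-temperature-like).
#' @param target_domain domain whose loop is displaced in low-pH-like mode.
#' @param loop_displacement final loop displacement in Angstrom.
#' @param interface_separation final inter-chain separation in Angstrom.
#' @param seed master seed; replicate r uses seed * 1000 + r.
#' @param occupancy optional named/unnamed vector of per-bridge occupancy
#'   fractions overriding the mode's designed schedule.
#' @return a `stress_profile`.
#' @export
stress_profile <- function(mode = c("reference", "low_ph_like", "high_temp_like"),
                           sigma = NULL, target_domain = "CL",
                           loop_displacement = 5, interface_separation = 10,
                           seed = 1L, occupancy = NULL) {
  mode <- match.arg(mode)
  sigma <- sigma %||% switch(mode, reference = 0.25, low_ph_like = 0.25,
                             high_temp_like = 0.6)
  if (sigma < 0) stopf("jitter sigma must be >= 0")
  if (!all(is.finite(c(loop_displacement, interface_separation))))
    stopf("ramps must be finite")
  structure(list(mode = mode, sigma = sigma, target_domain = target_domain,
                 loop_displacement = loop_displacement,
                 interface_separation = interface_separation,
                 seed = as.integer(seed), occupancy = occupancy),
            class = "stress_profile")
}

#' Simulate replicate stress trajectories with known ground truth
#'
#' Frames are the base structure plus i.i.d. Gaussian jitter and the
#' profile's deterministic schedule: a linear loop-displacement ramp
#' (low-pH-like), a linear inter-chain separation ramp (high-temperature-
#' like), and per-bridge on/off schedules in which bridge b is "on" for
#' the first round(p_b * n_frames) frames (its acidic oxygens sit at the
#' designed 3.0 Angstrom from the basic nitrogen, else at 4.6).  Designed
#' bridge atoms follow their residues' rigid motion but receive no jitter,
#' so scheduled occupancies are recovered exactly.  Replicate seeds are
#' seed * 1000 + replicate, so replicate sets are reproducible
#' independently.
#'
#' @param fab a `toy_fab` bundle.
#' @param profile a `stress_profile`.
#' @param n_frames frames per replicate (default 1001, i.e. 100 ns at the
#'   default 0.1 ns interval).
#' @param n_replicates number of replicates (default 6).
#' @param frame_interval_ns frame spacing in ns.
#' @return list of `fab_trajectory`, with attribute `ground_truth` (mode,
#'   seeds, ramps, bridge schedule with exact expected occurrences).
#' @export
simulate_stress_trajectory <- function(fab, profile, n_frames = 1001L,
                                       n_replicates = 6L,
                                       frame_interval_ns = 0.1) {
  stopifnot(inherits(fab, "toy_fab"), inherits(profile, "stress_profile"))
  if (n_frames < 2) stopf("need at least 2 frames")
  base <- get_coords(fab$structure)
  n_atoms <- nrow(base)
  br <- fab$bridges
  p <- profile$occupancy %||% fab$spec$schedules[[profile$mode]]
  if (length(p) != nrow(br)) stopf("occupancy vector must have %d entries", nrow(br))
  k_on <- round(p * n_frames)
  jitter_idx <- setdiff(seq_len(n_atoms), fab$groups$bridge_idx)
  loop_idx <- fab$groups$loop_idx[[profile$target_domain]]
  heavy_idx <- fab$groups$heavy_idx
  loop_dir <- c(0, 0, -1)   # away from the partner sheet for light-chain domains
  if (profile$target_domain %in% c("VH", "CH1")) loop_dir <- c(0, 0, 1)
  out <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    set.seed((profile$seed * 1000 + rep_i) %% 2147483647L)
    coords <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      s <- (f - 1) / (n_frames - 1)
      xyz <- base
      if (profile$sigma > 0)
        xyz[jitter_idx, ] <- xyz[jitter_idx, ] +
          matrix(rnorm(length(jitter_idx) * 3, sd = profile$sigma), ncol = 3)
      if (profile$mode == "low_ph_like")
        xyz[loop_idx, ] <- sweep(xyz[loop_idx, , drop = FALSE], 2,
                                 s * profile$loop_displacement * loop_dir, "+")
      if (profile$mode == "high_temp_like")
        xyz[heavy_idx, 3] <- xyz[heavy_idx, 3] + s * profile$interface_separation
      d <- ifelse(f <= k_on, fab$spec$d_on, fab$spec$d_off)
      u <- cbind(br$ux, br$uy, br$uz); pp <- cbind(br$px, br$py, br$pz)
      o1 <- xyz[br$ref_n_idx, , drop = FALSE] + d * u
      xyz[br$o1_idx, ] <- o1
      xyz[br$o2_idx, ] <- o1 + 0.9 * pp
      coords[, , f] <- xyz
    }
    out[[rep_i]] <- new_fab_trajectory(fab$structure, coords, frame_interval_ns)
  }
  attr(out, "ground_truth") <- list(
    mode = profile$mode, master_seed = profile$seed,
    replicate_seeds = profile$seed * 1000 + seq_len(n_replicates),
    n_frames = n_frames, sigma = profile$sigma,
    target_domain = profile$target_domain,
    loop_displacement = if (profile$mode == "low_ph_like") profile$loop_displacement else 0,
    interface_separation = if (profile$mode == "high_temp_like") profile$interface_separation else 0,
    bridge_schedule = data.frame(
      acid_resno = br$acid_resno, base_resno = br$base_resno,
      acid_resname = br$acid_resname,
      p = p, k_on = k_on, occurrence_pct = 100 * k_on / n_frames))
  out
}

#' Write a complete synthetic fixture set to disk
#'
#' Builds the mini-Fab, simulates the requested condition classes, and
#' writes the reference structure, multi-model PDB trajectories, a
#' ground-truth JSON and a ready-to-run analysis config.
#'
#' @param dir output directory (created if needed).
#' @param n_frames,n_replicates trajectory size per condition.
#' @param seed master seed.
#' @param modes condition classes to simulate.
#' @param spec a `toy_fab_spec`.
#' @return invisible list with the fixture paths and the `toy_fab`.
#' @export
write_toy_fixture <- function(dir, n_frames = 201L, n_replicates = 6L,
                              seed = 1L,
                              modes = c("reference", "low_ph_like", "high_temp_like"),
                              spec = toy_fab_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fab <- build_toy_fab(spec)
  ref_pdb <- file.path(dir, "reference.pdb")
  write_structure(fab$structure, ref_pdb)
  gt <- list()
  traj_files <- list()
  for (mode in modes) {
    prof <- stress_profile(mode, seed = seed)
    trajs <- simulate_stress_trajectory(fab, prof, n_frames = n_frames,
                                        n_replicates = n_replicates)
    files <- vapply(seq_along(trajs), function(r) {
      f <- file.path(dir, sprintf("traj_%s_rep%d.pdb", mode, r))
      write_trajectory(trajs[[r]], f)
      f
    }, "")
    traj_files[[mode]] <- files
    gt[[mode]] <- attr(trajs, "ground_truth")
  }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config <- list(
    structure = ref_pdb,
    frame_interval_ns = 0.1,
    reference = list(label = "reference",
                     trajectories = as.list(traj_files[["reference"]])),
    conditions = lapply(setdiff(modes, "reference"), function(m)
      list(label = m, trajectories = as.list(traj_files[[m]]))),
    regions = list(
      domains = lapply(fab$map$domains, as.integer),
      interfaces = lapply(fab$map$interfaces, as.character),
      strands = lapply(unclass(fab$smap), as.integer),
      aprs = lapply(unclass(fab$aprs), as.integer)))
  yaml::write_yaml(config, file.path(dir, "run.yaml"))
  invisible(list(dir = dir, fab = fab, config = file.path(dir, "run.yaml"),
                 ground_truth = gt, trajectories = traj_files,
                 reference_pdb = ref_pdb))
}
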