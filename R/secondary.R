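# Minimal Kabsch-Sander secondary structure: backbone hydrogen-bond
# energies, beta-bridge/ladder detection, per-strand occupancy statistics.
#
# Only the extended (E) state is assigned; helices, turns and isolated
# bridges map to "-".  The analyses here are exclusively about beta-strand
# occupancy, which is all the comparative reports use.

#' Kabsch-Sander hydrogen-bond parameters
#'
#' @param coupling electrostatic coupling constant q1*q2*f in kcal*A/mol
#'   (default 27.888).
#' @param cutoff bond-energy cutoff in kcal/mol (default -0.5, must be
#'   negative); a bond exists iff E < cutoff (strict).
#' @param nh_length amide N-H bond length in Angstrom (default 1.00).
#' @return an `hbond_params` list.
#' @export
hbond_params <- function(coupling = 27.888, cutoff = -0.5, nh_length = 1.00) {
  if (cutoff >= 0) stopf("energy cutoff must be negative")
  structure(list(coupling = coupling, cutoff = cutoff, nh_length = nh_length),
            class = "hbond_params")
}

# per-residue backbone atom indices; NA where an atom is missing
backbone_index <- function(structure) {
  at <- structure$atoms
  res <- unique(data.frame(resno = at$resno, chain = at$chain,
                           resname = at$resname)[!duplicated(at$resno), ])
  res <- res[order(res$resno), , drop = FALSE]
  find <- function(nm) {
    idx <- match(paste(res$resno, nm), paste(at$resno, at$name))
    idx
  }
  data.frame(resno = res$resno, chain = res$chain, resname = res$resname,
             iN = find("N"), iCA = find("CA"), iC = find("C"), iO = find("O"),
             stringsAsFactors = FALSE)
}

#' Place backbone amide hydrogens on a heavy-atom model
#'
#' H is placed 1.00 Angstrom from the backbone N along the direction of the
#' previous residue's C=O bond (from O towards C), the standard
#' reconstruction for the Kabsch-Sander energy on models without explicit
#' hydrogens.  The first residue of each chain and prolines carry no H and
#' are never donors; residues with missing backbone atoms are skipped with
#' a warning.
#'
#' @param structure a `fab_structure`.
#' @param frame coordinates (default: the structure's own).
#' @param params an `hbond_params`.
#' @return matrix n_residues x 3 of H coordinates, NA rows where no H is
#'   placed; rownames are residue numbers.
#' @export
place_amide_hydrogens <- function(structure, frame = NULL,
                                  params = hbond_params()) {
  bb <- backbone_index(structure)
  xyz <- if (is.null(frame)) get_coords(structure) else get_coords(frame)
  n <- nrow(bb)
  h <- matrix(NA_real_, n, 3, dimnames = list(bb$resno, c("x", "y", "z")))
  incomplete <- is.na(bb$iN) | is.na(bb$iCA) | is.na(bb$iC) | is.na(bb$iO)
  if (any(incomplete))
    warnf("%d residue(s) with missing backbone atoms skipped", sum(incomplete))
  for (i in seq_len(n)) {
    if (incomplete[i] || bb$resname[i] == "PRO") next
    if (i == 1L || bb$chain[i] != bb$chain[i - 1L] ||
        bb$resno[i] != bb$resno[i - 1L] + 1L || incomplete[i - 1L]) next
    cprev <- xyz[bb$iC[i - 1L], ]
    oprev <- xyz[bb$iO[i - 1L], ]
    u <- cprev - oprev
    u <- u / sqrt(sum(u^2))
    h[i, ] <- xyz[bb$iN[i], ] + params$nh_length * u
  }
  h
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' E = coupling * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) in kcal/mol, between
#' a donor amide (N, H) and an acceptor carbonyl (C, O).  Atoms closer than
#' 0.5 Angstrom are treated as a clash: the energy is set to -9.9 (the DSSP
#' convention) and flagged with a warning.
#'
#' @param n,h donor backbone N and amide H coordinates (length-3).
#' @param c_,o acceptor backbone C and O coordinates (length-3).
#' @param params an `hbond_params`.
#' @return energy in kcal/mol (NA if the donor has no H).
#' @export
hbond_energy <- function(n, h, c_, o, params = hbond_params()) {
  if (anyNA(h)) return(NA_real_)
  d <- function(a, b) sqrt(sum((a - b)^2))
  r <- c(d(o, n), d(c_, h), d(o, h), d(c_, n))
  if (any(r < 0.5)) {
    warnf("clashing backbone atoms (distance < 0.5 A): energy set to -9.9")
    return(-9.9)
  }
  params$coupling * (1 / r[1] + 1 / r[2] - 1 / r[3] - 1 / r[4])
}

# vectorised donor->acceptor H-bond matrix over candidate residue pairs
.hbond_matrix <- function(bb, xyz, hcoord, params, ca_prefilter = 9.0) {
  n <- nrow(bb)
  hb <- matrix(FALSE, n, n)
  ok <- !(is.na(bb$iN) | is.na(bb$iCA) | is.na(bb$iC) | is.na(bb$iO))
  ca <- xyz[ifelse(is.na(bb$iCA), 1L, bb$iCA), , drop = FALSE]
  d2 <- cross_dist2(ca, ca)
  has_h <- !is.na(hcoord[, 1])
  cand <- which(d2 < ca_prefilter^2, arr.ind = TRUE)
  cand <- cand[cand[, 1] != cand[, 2] & has_h[cand[, 1]] &
                 ok[cand[, 1]] & ok[cand[, 2]], , drop = FALSE]
  if (nrow(cand) == 0L) return(hb)
  di <- cand[, 1]; ai <- cand[, 2]
  np <- xyz[bb$iN[di], , drop = FALSE]; hp <- hcoord[di, , drop = FALSE]
  cp <- xyz[bb$iC[ai], , drop = FALSE]; op <- xyz[bb$iO[ai], , drop = FALSE]
  dist <- function(a, b) sqrt(rowSums((a - b)^2))
  r_on <- dist(op, np); r_ch <- dist(cp, hp)
  r_oh <- dist(op, hp); r_cn <- dist(cp, np)
  e <- params$coupling * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  e[r_on < 0.5 | r_ch < 0.5 | r_oh < 0.5 | r_cn < 0.5] <- -9.9
  hb[cand[e < params$cutoff, , drop = FALSE]] <- TRUE
  hb
}

#' Assign beta-strand state to every residue of a frame
#'
#' Computes Kabsch-Sander backbone hydrogen bonds (with reconstructed amide
#' hydrogens and a CA-CA < 9 Angstrom prefilter) and marks beta bridges:
#' parallel between residues i and j iff (Hbond(i-1 -> j) and
#' Hbond(j -> i+1)) or (Hbond(j-1 -> i) and Hbond(i -> j+1)); antiparallel
#' iff (Hbond(i -> j) and Hbond(j -> i)) or (Hbond(i-1 -> j+1) and
#' Hbond(j-1 -> i+1)).  Residues in ladders of at least two consecutive
#' bridges are labelled "E"; isolated bridges and everything else are "-".
#'
#' @param structure a `fab_structure`.
#' @param frame coordinates (default: the structure's own).
#' @param params an `hbond_params`.
#' @return named character vector over residues ("E" or "-").
#' @export
assign_beta <- function(structure, frame = NULL, params = hbond_params()) {
  bb <- backbone_index(structure)
  xyz <- if (is.null(frame)) get_coords(structure) else get_coords(frame)
  hcoord <- suppressWarnings(place_amide_hydrogens(structure, xyz, params))
  hb <- .hbond_matrix(bb, xyz, hcoord, params)
  n <- nrow(bb)
  ss <- setNames(rep("-", n), bb$resno)
  if (n < 5L) return(ss)
  # adjacency in sequence (same chain, consecutive numbering)
  adj <- c(FALSE, bb$chain[-1] == bb$chain[-n] & bb$resno[-1] == bb$resno[-n] + 1L)
  hbs <- function(i, j) {  # safe lookup with bounds + adjacency handled upstream
    i >= 1 & i <= n & j >= 1 & j <= n &
      hb[cbind(pmin(pmax(i, 1), n), pmin(pmax(j, 1), n))]
  }
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] > 2, , drop = FALSE]
  i <- pairs[, 1]; j <- pairs[, 2]
  prev_ok <- function(k) k - 1 >= 1 & adj[pmax(k, 2)]
  next_ok <- function(k) k + 1 <= n & c(adj[-1], FALSE)[pmin(k, n - 1)]
  par <- (prev_ok(i) & next_ok(i) & hbs(i - 1, j) & hbs(j, i + 1)) |
         (prev_ok(j) & next_ok(j) & hbs(j - 1, i) & hbs(i, j + 1))
  anti <- (hbs(i, j) & hbs(j, i)) |
          (prev_ok(i) & next_ok(j) & prev_ok(j) & next_ok(i) &
             hbs(i - 1, j + 1) & hbs(j - 1, i + 1))
  bridge <- par | anti
  if (!any(bridge)) return(ss)
  bi <- i[bridge]; bj <- j[bridge]
  btype <- ifelse(anti[bridge], "A", "P")
  key <- paste(bi, bj, btype)
  in_ladder <- rep(FALSE, length(bi))
  succ_a <- paste(bi + 1, bj - 1, "A"); pred_a <- paste(bi - 1, bj + 1, "A")
  succ_p <- paste(bi + 1, bj + 1, "P"); pred_p <- paste(bi - 1, bj - 1, "P")
  is_a <- btype == "A"
  in_ladder[is_a] <- (succ_a[is_a] %in% key) | (pred_a[is_a] %in% key)
  in_ladder[!is_a] <- (succ_p[!is_a] %in% key) | (pred_p[!is_a] %in% key)
  ss[unique(c(bi[in_ladder], bj[in_ladder]))] <- "E"
  ss
}

#' Per-residue and per-strand beta occupancy of one trajectory
#'
#' @param traj a `fab_trajectory`.
#' @param smap a `strand_map`.
#' @param params an `hbond_params`.
#' @return list with `residue` (named vector, % of frames labelled E) and
#'   `strand` (named vector, mean over each strand's residues, in %).
#' @export
strand_occupancy <- function(traj, smap, params = hbond_params()) {
  bb <- backbone_index(traj$topology)
  nf <- n_frames(traj)
  e_count <- setNames(numeric(nrow(bb)), bb$resno)
  for (f in seq_len(nf)) {
    ss <- assign_beta(traj$topology, traj$coords[, , f], params)
    e_count <- e_count + (ss == "E")
  }
  res_occ <- 100 * e_count / nf
  strand_occ <- vapply(names(smap), function(nm) {
    iv <- smap[[nm]]
    sel <- as.integer(names(res_occ)) >= iv[1] & as.integer(names(res_occ)) <= iv[2]
    mean(res_occ[sel])
  }, 1.0)
  list(residue = res_occ, strand = strand_occ)
}

#' Per-strand beta-occupancy change between conditions
#'
#' For each replicate pairing, the per-strand occupancy (percentage of
#' frame-time its residues are labelled E, averaged over residues) is
#' computed for the stress and reference trajectories, and the change is
#' either relative (100 x (occ_stress - occ_ref) / occ_ref, the default) or
#' an absolute percentage-point difference.  Mean and SEM are taken over
#' replicate pairings.  Strands never beta in the reference yield NA with a
#' warning, not infinities.
#'
#' @param stress,reference lists of `fab_trajectory` (paired by index).
#' @param smap a `strand_map`.
#' @param relative relative percent change (default) or percentage-point
#'   difference.
#' @param params an `hbond_params`.
#' @return data.frame with columns strand, occ_ref, occ_stress, change,
#'   sem, n (occupancies are replicate means, in %).
#' @export
strand_occupancy_change <- function(stress, reference, smap, relative = TRUE,
                                    params = hbond_params()) {
  if (length(stress) != length(reference))
    stopf("stress and reference must have the same number of replicates")
  n_rep <- length(stress)
  occ_s <- sapply(stress, function(t) strand_occupancy(t, smap, params)$strand)
  occ_r <- sapply(reference, function(t) strand_occupancy(t, smap, params)$strand)
  occ_s <- matrix(occ_s, ncol = n_rep); occ_r <- matrix(occ_r, ncol = n_rep)
  rownames(occ_s) <- rownames(occ_r) <- names(smap)
  if (relative) {
    change <- 100 * (occ_s - occ_r) / occ_r
    change[occ_r == 0] <- NA_real_
    if (any(occ_r == 0))
      warnf("strand(s) with zero reference occupancy: relative change undefined")
  } else {
    change <- occ_s - occ_r
  }
  data.frame(strand = names(smap),
             occ_ref = rowMeans(occ_r),
             occ_stress = rowMeans(occ_s),
             change = rowMeans(change),
             sem = if (n_rep > 1) apply(change, 1, sd) / sqrt(n_rep) else 0,
             n = n_rep,
             row.names = NULL, stringsAsFactors = FALSE)
}
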