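# Structures, trajectories and the Fab-style coordinate model.
#
# PDB parsing and writing are delegated to bio3d; this layer adds the
# validation, filtering and renumbering conventions the analyses rely on:
# hydrogens dropped (heavy-atom model), first altloc kept, insertion codes
# rejected, and chains renumbered to a single continuous residue axis
# (light chain 1-214, heavy chain continuing at 215 for the full Fab).

.as_pdb_file <- function(pdb) {
  # accept a file path or raw PDB text (single string or vector of lines)
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  tf <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), tf)
  tf
}

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    stopf("empty input: no ATOM/HETATM records found")
  at <- lines[is_atom]
  lineno <- which(is_atom)
  for (fld in list(c(31, 38, "x"), c(39, 46, "y"), c(47, 54, "z"))) {
    v <- suppressWarnings(as.numeric(substr(at, as.integer(fld[1]), as.integer(fld[2]))))
    if (anyNA(v))
      stopf("malformed %s coordinate field at line %d: %s",
            fld[3], lineno[which(is.na(v))[1]], trimws(at[which(is.na(v))[1]]))
  }
  ins <- substr(at, 27, 27)
  if (any(ins != " "))
    stopf("insertion codes are not supported (line %d)", lineno[which(ins != " ")[1]])
  invisible(TRUE)
}

.infer_element <- function(elesy, name) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # strip leading digits then take the leading letter(s); two-letter
    # elements other than these never occur in the heavy-atom protein model
    nm <- gsub("^[0-9']+", "", trimws(name[miss]))
    first <- toupper(substr(nm, 1, 1))
    el[miss] <- first
  }
  el
}

.renumber_chains <- function(resno, chain) {
  # each chain after the first continues the numbering of the previous one,
  # so a heavy chain starting at 1 after a 214-residue light chain becomes
  # 215-442 (continuous Fab numbering)
  chains <- unique(chain)
  if (length(chains) <= 1L) return(resno)
  out <- resno
  running_max <- 0L
  for (ch in chains) {
    sel <- chain == ch
    out[sel] <- resno[sel] - min(resno[sel]) + running_max + 1L
    running_max <- max(out[sel])
  }
  out
}

.atoms_from_bio3d <- function(pdb, keep_h = FALSE, renumber = TRUE) {
  at <- pdb$atom
  keep <- !duplicated(paste(at$chain, at$resno, at$insert, at$elety))
  at <- at[keep, , drop = FALSE]
  element <- .infer_element(at$elesy, at$elety)
  if (!keep_h) {
    hv <- element != "H"
    at <- at[hv, , drop = FALSE]
    element <- element[hv]
    keep[keep] <- hv
  }
  if (nrow(at) == 0L) stopf("empty input: no heavy atoms after filtering")
  resno <- at$resno
  if (renumber) resno <- .renumber_chains(at$resno, at$chain)
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = element, resno = resno,
                      resname = trimws(at$resid), chain = at$chain,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, keep = keep)
}

.validate_structure <- function(atoms) {
  if (any(atoms$resno < 1L)) stopf("residue numbers must be >= 1")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stopf("non-finite coordinates in structure")
  invisible(TRUE)
}

new_fab_structure <- function(atoms, title = "") {
  .validate_structure(atoms)
  structure(list(atoms = atoms, title = title), class = "fab_structure")
}

#' Read a protein structure from a PDB file or text
#'
#' Parses fixed-width ATOM/HETATM records (via bio3d), drops hydrogens by
#' default, keeps the first alternate location of each atom, rejects
#' insertion codes, and renumbers chains onto one continuous residue axis:
#' the first chain keeps its numbering and every later chain continues where
#' the previous one ended (a heavy chain numbered from 1 after a 214-residue
#' light chain becomes residues 215 onwards).
#'
#' @param pdb path to a PDB file, or PDB text.
#' @param keep_h keep hydrogen atoms (default FALSE; all analyses are
#'   heavy-atom).
#' @param renumber apply the continuous chain renumbering rule.
#' @return a `fab_structure`: list with `atoms` (data.frame: serial, name,
#'   element, resno, resname, chain, x, y, z) and `title`.
#' @export
read_structure <- function(pdb, keep_h = FALSE, renumber = TRUE) {
  file <- .as_pdb_file(pdb)
  lines <- readLines(file, warn = FALSE)
  .validate_pdb_lines(lines)
  invisible(utils::capture.output(
    parsed <- suppressWarnings(bio3d::read.pdb(file, verbose = FALSE))))
  res <- .atoms_from_bio3d(parsed, keep_h = keep_h, renumber = renumber)
  title <- ""
  tl <- grep("^TITLE", lines, value = TRUE)
  if (length(tl)) title <- trimws(substr(tl[1], 11, nchar(tl[1])))
  new_fab_structure(res$atoms, title = title)
}

#' Read a multi-model PDB trajectory
#'
#' MODEL/ENDMDL blocks become ordered frames sharing the topology of the
#' first model.  All models must contain the same number of atoms in the
#' same order.
#'
#' @param pdb path or PDB text with MODEL records (a file without MODEL
#'   records yields a single-frame trajectory).
#' @param frame_interval_ns time between saved frames in ns (default 0.1).
#' @inheritParams read_structure
#' @return a `fab_trajectory`: list with `topology` (`fab_structure`),
#'   `coords` (array n_atoms x 3 x n_frames) and `frame_interval_ns`.
#' @export
read_trajectory <- function(pdb, frame_interval_ns = 0.1, keep_h = FALSE,
                            renumber = TRUE) {
  if (frame_interval_ns <= 0) stopf("frame_interval_ns must be > 0")
  file <- .as_pdb_file(pdb)
  lines <- readLines(file, warn = FALSE)
  .validate_pdb_lines(lines)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1L) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(i) {
      blk <- rec[bounds[i]:(bounds[i + 1L] - 1L)]
      sum(blk %in% c("ATOM  ", "HETATM"))
    }, 1L)
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1])[1]
      stopf("inconsistent atom count across models: model 1 has %d atoms, model %d has %d",
            counts[1], bad, counts[bad])
    }
  }
  invisible(utils::capture.output(
    parsed <- suppressWarnings(bio3d::read.pdb(file, multi = TRUE, verbose = FALSE))))
  res <- .atoms_from_bio3d(parsed, keep_h = keep_h, renumber = renumber)
  topo <- new_fab_structure(res$atoms)
  xyz <- parsed$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- bio3d::atom2xyz(which(res$keep))
  xyz <- xyz[, cols, drop = FALSE]
  n_frames <- nrow(xyz)
  n_atoms <- nrow(res$atoms)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new_fab_trajectory(topo, coords, frame_interval_ns)
}

new_fab_trajectory <- function(topology, coords, frame_interval_ns = 0.1) {
  stopifnot(inherits(topology, "fab_structure"))
  if (length(dim(coords)) != 3L || dim(coords)[1] != nrow(topology$atoms))
    stopf("frame shape does not match topology: %d atoms expected",
          nrow(topology$atoms))
  if (frame_interval_ns <= 0) stopf("frame_interval_ns must be > 0")
  structure(list(topology = topology, coords = coords,
                 frame_interval_ns = frame_interval_ns),
            class = "fab_trajectory")
}

#' Coordinates of a structure or of one trajectory frame
#'
#' @param x a `fab_structure` or `fab_trajectory`.
#' @param frame frame index (trajectories only).
#' @return numeric matrix, one row per atom, columns x/y/z.
#' @export
get_coords <- function(x, frame = NULL) {
  if (inherits(x, "fab_structure")) {
    return(cbind(x = x$atoms$x, y = x$atoms$y, z = x$atoms$z))
  }
  if (inherits(x, "fab_trajectory")) {
    if (is.null(frame)) stopf("frame index required for a trajectory")
    return(x$coords[, , frame])
  }
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stopf("cannot extract coordinates from object of class %s", class(x)[1])
}

#' @export
print.fab_structure <- function(x, ...) {
  cat(sprintf("fab_structure: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), length(unique(x$atoms$resno)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' @export
print.fab_trajectory <- function(x, ...) {
  nf <- dim(x$coords)[3]
  cat(sprintf("fab_trajectory: %d frames x %d atoms, %.1f ns at %.3g ns/frame\n",
              nf, dim(x$coords)[1], (nf - 1) * x$frame_interval_ns,
              x$frame_interval_ns))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `fab_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Frame times in ns (first frame at 0)
#' @param traj a `fab_trajectory`.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$frame_interval_ns

# ---- writing ---------------------------------------------------------------

.write_pdb_atoms <- function(atoms, xyz, file, b = NULL) {
  if (is.null(b)) b <- rep(0, nrow(atoms))
  bio3d::write.pdb(file = file, xyz = as.vector(t(xyz)),
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resno, resid = atoms$resname,
                   eleno = atoms$serial, elety = atoms$name,
                   chain = atoms$chain, o = rep(1, nrow(atoms)),
                   b = b, elesy = atoms$element)
  invisible(file)
}

#' Write a structure to a PDB file
#'
#' @param structure a `fab_structure`.
#' @param file output path; when NULL the PDB text is returned instead.
#' @param b optional per-atom temperature factors.
#' @return the PDB text, invisibly.
#' @export
write_structure <- function(structure, file = NULL, b = NULL) {
  out <- file %||% tempfile(fileext = ".pdb")
  .write_pdb_atoms(structure$atoms, get_coords(structure), out, b = b)
  txt <- readLines(out, warn = FALSE)
  if (is.null(file)) unlink(out)
  invisible(txt)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `fab_trajectory`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  at <- traj$topology$atoms
  con <- file(file, "w")
  on.exit(close(con))
  tf <- tempfile(fileext = ".pdb")
  for (f in seq_len(n_frames(traj))) {
    .write_pdb_atoms(at, traj$coords[, , f], tf)
    body <- readLines(tf, warn = FALSE)
    body <- body[!grepl("^END", body)]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  unlink(tf)
  invisible(file)
}

#' Project per-residue scores onto a structure's temperature factors
#'
#' Writes each residue's score into the B-factor column of every atom of
#' that residue, clamped to the PDB column range -9.99 to 999.99.  Residues
#' without a score get 0.00.  A round-trip read recovers the values to two
#' decimals.  Used to visualise per-residue differences (e.g. change in RMSF
#' or native-contact fraction between a stress and a reference condition) in
#' any molecular viewer.
#'
#' @param structure a `fab_structure`.
#' @param scores named numeric vector, names = residue numbers.
#' @param file optional output path.
#' @return the projected PDB text, invisibly.
#' @export
write_score_projection <- function(structure, scores, file = NULL) {
  if (length(scores) == 0L) stopf("no scores supplied")
  if (is.null(names(scores))) stopf("scores must be named by residue number")
  if (!all(is.finite(scores))) {
    bad <- names(scores)[!is.finite(scores)]
    stopf("non-finite score for residue %s", paste(bad, collapse = ", "))
  }
  clamped <- pmin(pmax(scores, -9.99), 999.99)
  if (any(clamped != scores))
    warnf("%d score(s) clamped to the PDB B-factor range [-9.99, 999.99]",
          sum(clamped != scores))
  b <- rep(0, nrow(structure$atoms))
  idx <- match(as.character(structure$atoms$resno), names(scores))
  b[!is.na(idx)] <- clamped[idx[!is.na(idx)]]
  write_structure(structure, file = file, b = b)
}

# ---- region model ----------------------------------------------------------

#' Domain map: named residue intervals plus interface pairs
#'
#' @param domains named list of inclusive residue intervals `c(start, end)`;
#'   intervals must not overlap.
#' @param interfaces named list of ordered pairs of domain names.
#' @return a `domain_map`.
#' @export
domain_map <- function(domains, interfaces = list()) {
  for (nm in names(domains)) {
    iv <- domains[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2])
      stopf("domain %s: interval must be c(start, end) with start <= end", nm)
  }
  if (length(domains) > 1L) {
    ivs <- do.call(rbind, domains)
    ord <- order(ivs[, 1])
    ivs <- ivs[ord, , drop = FALSE]
    if (any(ivs[-1, 1] <= ivs[-nrow(ivs), 2]))
      stopf("domain intervals overlap")
  }
  for (nm in names(interfaces)) {
    pair <- interfaces[[nm]]
    if (length(pair) != 2L || !all(pair %in% names(domains)))
      stopf("interface %s must name two domains in the map", nm)
  }
  structure(list(domains = domains, interfaces = interfaces),
            class = "domain_map")
}

#' Default Fab domain map
#'
#' Continuous numbering over both chains: VL 1-108, CL 109-214 (light
#' chain), VH 215-334, CH1 335-429 (heavy chain), with the VL-VH and CL-CH1
#' interfaces.  Hinge residues 430-442 belong to no domain: they are
#' excluded from domain regions but retained in whole-protein metrics.
#'
#' @return a `domain_map`.
#' @export
fab_domain_map <- function() {
  domain_map(list(VL = c(1, 108), CL = c(109, 214),
                  VH = c(215, 334), CH1 = c(335, 429)),
             list("VL-VH" = c("VL", "VH"), "CL-CH1" = c("CL", "CH1")))
}

#' Region names of a domain map
#' @param map a `domain_map`.
#' @export
region_names <- function(map) c(names(map$domains), names(map$interfaces))

#' Select the atoms of a region
#'
#' For a domain, the indices of all atoms whose residue lies in the domain
#' interval; for an interface, a list of the two domains' index vectors (in
#' the interface's declared order).
#'
#' @param structure a `fab_structure` (or trajectory topology).
#' @param map a `domain_map`.
#' @param region a domain or interface name.
#' @return integer vector of atom indices, or a list of two such vectors.
#' @export
select_region <- function(structure, map, region) {
  if (inherits(structure, "fab_trajectory")) structure <- structure$topology
  resno <- structure$atoms$resno
  pick <- function(dom) {
    iv <- map$domains[[dom]]
    idx <- which(resno >= iv[1] & resno <= iv[2])
    if (length(idx) == 0L)
      warnf("region %s covers no residues present in the structure", dom)
    idx
  }
  if (region %in% names(map$domains)) return(pick(region))
  if (region %in% names(map$interfaces)) {
    pair <- map$interfaces[[region]]
    return(list(pick(pair[1]), pick(pair[2])))
  }
  stopf("unknown region '%s'; valid regions: %s", region,
        paste(region_names(map), collapse = ", "))
}

#' Strand map: strand label to inclusive residue interval
#'
#' @param intervals named list of `c(start, end)` intervals; labels unique.
#' @param map optional `domain_map`; when given, each strand must lie inside
#'   exactly one domain.
#' @return a `strand_map`.
#' @export
strand_map <- function(intervals, map = NULL) {
  if (anyDuplicated(names(intervals))) stopf("strand labels must be unique")
  for (nm in names(intervals)) {
    iv <- intervals[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2])
      stopf("strand %s: interval must be c(start, end) with start <= end", nm)
    if (!is.null(map)) {
      inside <- vapply(map$domains, function(d) iv[1] >= d[1] && iv[2] <= d[2], TRUE)
      if (sum(inside) != 1L)
        stopf("strand %s does not lie inside exactly one domain", nm)
    }
  }
  structure(intervals, class = "strand_map")
}

#' Standard Fab strand labels
#'
#' The 34 beta strands of a Fab under the usual nomenclature: 9 in VL (A-I)
#' and 7 in CL (J-P) on the light chain; 10 in VH (A-J) and 8 in CH1 (K-R)
#' on the heavy chain.  Labels are prefixed with their domain.
#'
#' @return character vector of 34 labels.
#' @export
fab_strand_labels <- function() {
  c(paste0("VL_", LETTERS[1:9]), paste0("CL_", LETTERS[10:16]),
    paste0("VH_", LETTERS[1:10]), paste0("CH1_", LETTERS[11:18]))
}

#' APR set: named aggregation-prone-region residue intervals
#'
#' @param intervals named list of `c(start, end)`.
#' @param max_residue upper bound for interval ends (default 442).
#' @return an `apr_set`.
#' @export
apr_set <- function(intervals, max_residue = 442) {
  for (nm in names(intervals)) {
    iv <- intervals[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 1 || iv[2] > max_residue)
      stopf("APR %s: interval must lie within 1-%d with start <= end", nm, max_residue)
  }
  structure(intervals, class = "apr_set")
}

#' Default Fab APR set
#'
#' The seven consensus aggregation-prone regions of the Fab model: residues
#' 31-36, 47-51, 114-118 and 129-139 in the light chain, and 261-265,
#' 325-329 and 387-402 in the heavy chain.
#'
#' @return an `apr_set`.
#' @export
fab_apr_set <- function() {
  apr_set(list("APR_31-36" = c(31, 36), "APR_47-51" = c(47, 51),
               "APR_114-118" = c(114, 118), "APR_129-139" = c(129, 139),
               "APR_261-265" = c(261, 265), "APR_325-329" = c(325, 329),
               "APR_387-402" = c(387, 402)))
}

# atom indices covered by a set of residue numbers
residues_to_atoms <- function(structure, residues) {
  which(structure$atoms$resno %in% residues)
}
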