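# Salt-bridge detection and occurrence statistics.
#
# A salt bridge is recorded between an acidic and a basic residue whenever
# ANY qualifying side-chain oxygen-nitrogen atom pair is within the cutoff
# in a frame (residue-level any-atom rule; bridges are reported as residue
# pairs such as Glu195-Lys149).  Occurrence is the percentage of frames in
# which the bridge is formed.

#' Salt-bridge detection parameters
#'
#' @param cutoff O-N distance cutoff in Angstrom (default 3.2); a pair at
#'   exactly the cutoff counts as formed.
#' @param include_his also treat His ND1/NE2 as basic nitrogens (off by
#'   default: His participation depends on its protonation state).
#' @return a `salt_bridge_params` list with the acidic/basic atom-name sets
#'   (Asp OD1/OD2 and Glu OE1/OE2 vs Lys NZ and Arg NE/NH1/NH2).
#' @export
salt_bridge_params <- function(cutoff = 3.2, include_his = FALSE) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  basic <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (include_his) basic$HIS <- c("ND1", "NE2")
  structure(list(cutoff = cutoff, acidic = acidic, basic = basic,
                 include_his = include_his),
            class = "salt_bridge_params")
}

.charged_atoms <- function(structure, groups) {
  at <- structure$atoms
  sel <- logical(nrow(at))
  for (res in names(groups))
    sel <- sel | (at$resname == res & at$name %in% groups[[res]])
  which(sel)
}

#' Detect salt bridges in one frame
#'
#' @param frame coordinates for the full topology.
#' @param structure the matching `fab_structure` (provides residue/atom
#'   names).
#' @param params a `salt_bridge_params`.
#' @return data.frame with columns acid_resno, base_resno (unique residue
#'   pairs, possibly empty).
#' @export
detect_salt_bridges <- function(frame, structure, params = salt_bridge_params()) {
  frame <- get_coords(frame)
  ai <- .charged_atoms(structure, params$acidic)
  bi <- .charged_atoms(structure, params$basic)
  empty <- data.frame(acid_resno = integer(), base_resno = integer())
  if (length(ai) == 0L || length(bi) == 0L) return(empty)
  d2 <- cross_dist2(frame[ai, , drop = FALSE], frame[bi, , drop = FALSE])
  hit <- which(d2 <= params$cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  resno <- structure$atoms$resno
  pairs <- unique(data.frame(acid_resno = resno[ai[hit[, 1]]],
                             base_resno = resno[bi[hit[, 2]]]))
  pairs <- pairs[order(pairs$acid_resno, pairs$base_resno), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Salt-bridge occurrence percentages over a trajectory
#'
#' occurrence = 100 x (frames in which the bridge is detected) / (total
#' frames).  Pairs never formed are absent from the result (sparse map,
#' not zero-valued rows).
#'
#' @param traj a `fab_trajectory`.
#' @param params a `salt_bridge_params`.
#' @return data.frame with columns acid_resno, base_resno, occurrence.
#' @export
bridge_occurrence <- function(traj, params = salt_bridge_params()) {
  nf <- n_frames(traj)
  if (nf < 1L) stopf("empty trajectory")
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    det <- detect_salt_bridges(traj$coords[, , f], traj$topology, params)
    if (nrow(det) == 0L) next
    keys <- paste(det$acid_resno, det$base_resno, sep = "-")
    for (k in keys) assign(k, (counts[[k]] %||% 0L) + 1L, envir = counts)
  }
  keys <- ls(counts)
  if (length(keys) == 0L)
    return(data.frame(acid_resno = integer(), base_resno = integer(),
                      occurrence = numeric()))
  parts <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
  out <- data.frame(acid_resno = as.integer(parts[, 1]),
                    base_resno = as.integer(parts[, 2]),
                    occurrence = 100 * vapply(keys, function(k) counts[[k]], 1L) / nf)
  out <- out[order(-out$occurrence, out$acid_resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-replicate occurrence maps into an occurrence table
#'
#' The union of residue pairs across replicates is taken, missing entries
#' count as 0%, and the mean and SEM per pair are computed over replicates.
#' Rows are retained iff the replicate mean is at or above the threshold
#' (the threshold applies to the mean, not per replicate).
#'
#' @param tables list of per-replicate data.frames as returned by
#'   [bridge_occurrence()].
#' @param threshold report threshold in percent (default 10; 0 retains
#'   every pair seen in any replicate).
#' @return data.frame (class `occurrence_table`) with columns acid_resno,
#'   base_resno, rep1..repN, mean, sem.
#' @export
aggregate_occurrence <- function(tables, threshold = 10) {
  stopifnot(length(tables) >= 1L)
  keys <- unique(unlist(lapply(tables, function(t)
    paste(t$acid_resno, t$base_resno, sep = "-"))))
  if (length(keys) == 0L) {
    out <- data.frame(acid_resno = integer(), base_resno = integer(),
                      mean = numeric(), sem = numeric())
    class(out) <- c("occurrence_table", "data.frame")
    attr(out, "threshold") <- threshold
    return(out)
  }
  occ <- sapply(tables, function(t) {
    tk <- paste(t$acid_resno, t$base_resno, sep = "-")
    v <- t$occurrence[match(keys, tk)]
    v[is.na(v)] <- 0
    v
  })
  occ <- matrix(occ, nrow = length(keys))
  colnames(occ) <- paste0("rep", seq_len(ncol(occ)))
  n <- ncol(occ)
  m <- rowMeans(occ)
  sem <- if (n > 1) apply(occ, 1, sd) / sqrt(n) else rep(0, length(keys))
  parts <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
  out <- data.frame(acid_resno = as.integer(parts[, 1]),
                    base_resno = as.integer(parts[, 2]),
                    occ, mean = m, sem = sem)
  out <- out[out$mean >= threshold, , drop = FALSE]
  out <- out[order(-out$mean), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_table", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Count retained salt bridges per domain and interface
#'
#' A bridge counts for a domain when both partners lie in it, for an
#' interface when the partners lie in the interface's two domains (either
#' orientation).  Any other combination (including partners outside every
#' domain, e.g. hinge residues) goes into a labelled "other" bucket.
#'
#' @param table an `occurrence_table` (already thresholded).
#' @param map a `domain_map`.
#' @return data.frame with columns region, type (intra/interface/other),
#'   count, covering every domain and interface of the map plus "other".
#' @export
count_by_region <- function(table, map) {
  dom_of <- function(res) {
    for (nm in names(map$domains)) {
      iv <- map$domains[[nm]]
      if (res >= iv[1] && res <= iv[2]) return(nm)
    }
    NA_character_
  }
  regions <- c(names(map$domains), names(map$interfaces), "other")
  counts <- setNames(integer(length(regions)), regions)
  labels <- character(0)
  if (nrow(table) > 0) {
    for (r in seq_len(nrow(table))) {
      da <- dom_of(table$acid_resno[r]); db <- dom_of(table$base_resno[r])
      bucket <- "other"
      if (!is.na(da) && !is.na(db)) {
        if (da == db) bucket <- da
        else {
          for (nm in names(map$interfaces)) {
            pair <- map$interfaces[[nm]]
            if (setequal(c(da, db), pair)) { bucket <- nm; break }
          }
        }
      }
      if (bucket == "other")
        labels <- c(labels, paste(sort(c(ifelse(is.na(da), "none", da),
                                         ifelse(is.na(db), "none", db))), collapse = "-"))
      counts[bucket] <- counts[bucket] + 1L
    }
  }
  out <- data.frame(region = regions,
                    type = c(rep("intra", length(map$domains)),
                             rep("interface", length(map$interfaces)), "other"),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "other_pairs") <- unique(labels)
  out
}
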