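# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# atomic masses (u) for the elements of a heavy-atom protein model.
# unknown elements fall back to carbon with a warning (documented rule).
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)

element_masses <- function(elements) {
  m <- .element_masses[elements]
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    warnf("unknown element(s) %s assigned carbon mass", paste(bad, collapse = ", "))
    m[is.na(m)] <- .element_masses[["C"]]
  }
  unname(m)
}

# van der Waals radii (Angstrom) used by the surface module
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

vdw_radii <- function(elements) {
  r <- .vdw_radii[elements]
  if (anyNA(r)) {
    bad <- unique(elements[is.na(r)])
    warnf("unknown element(s) %s assigned carbon vdW radius", paste(bad, collapse = ", "))
    r[is.na(r)] <- .vdw_radii[["C"]]
  }
  unname(r)
}

#' Replicate mean and standard error
#'
#' Aggregates per-replicate series that share a common axis into per-point
#' mean and standard error of the mean (SEM, sample standard deviation over
#' the square root of the replicate count).  With a single replicate the SEM
#' is reported as 0 and flagged with a warning.
#'
#' @param values numeric matrix with one column per replicate (rows are the
#'   shared axis, e.g. time points or residues), or a list of equal-length
#'   numeric vectors.
#' @return data.frame with columns `mean`, `sem`, `n`.
#' @export
replicate_stats <- function(values) {
  if (is.list(values) && !is.data.frame(values)) {
    len <- unique(vapply(values, length, 1L))
    if (length(len) != 1L)
      stopf("replicate series have differing lengths: %s", paste(unique(len), collapse = ", "))
    values <- do.call(cbind, values)
  }
  values <- as.matrix(values)
  n <- ncol(values)
  if (n == 1L) {
    warnf("single replicate: SEM reported as 0")
    return(data.frame(mean = as.numeric(values[, 1]), sem = 0, n = 1L))
  }
  data.frame(mean = rowMeans(values),
             sem = apply(values, 1, sd) / sqrt(n),
             n = n)
}

# cross-set squared distances between two coordinate matrices (rows = points)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

# fixed-format number for byte-stable CSV output
fmt_num <- function(x) signif(x, 6)
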