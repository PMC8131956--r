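# Mutational-scan bookkeeping, stabilising-consensus intersection of
# externally computed ddG tables, alignment column entropy, and APR
# consensus construction.  ddG computation itself (FoldX/Rosetta) and APR
# predictor runs are external; their tables and per-residue calls are
# inputs here.

.aa1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Enumerate all single-point mutants of a sequence
#'
#' Every position is substituted by each of the 19 other standard amino
#' acids, so a length-L sequence yields exactly 19 x L mutations (8398 for
#' the 442-residue Fab).
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @return data.frame with columns position, wt, mut, id (e.g. "A15G");
#'   empty for an empty sequence.
#' @export
enumerate_single_mutants <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) == 0L)
    return(data.frame(position = integer(), wt = character(),
                      mut = character(), id = character()))
  bad <- which(!(aa %in% .aa1))
  if (length(bad))
    stopf("non-standard amino acid '%s' at position %d", aa[bad[1]], bad[1])
  position <- rep(seq_along(aa), each = 19L)
  wt <- aa[position]
  mut <- unlist(lapply(aa, function(a) setdiff(.aa1, a)), use.names = FALSE)
  data.frame(position = position, wt = wt, mut = mut,
             id = paste0(wt, position, mut), stringsAsFactors = FALSE)
}

#' Read or validate an external ddG table
#'
#' Sign convention: negative ddG = stabilising.  CSV schema:
#' position, wt, mut, ddg (and optionally source).
#'
#' @param x CSV path or data.frame.
#' @param source label for the predicting tool.
#' @return a validated `ddg_table` data.frame with an `id` column.
#' @export
read_ddg_table <- function(x, source = "external") {
  tab <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("position", "wt", "mut", "ddg")
  if (!all(need %in% names(tab)))
    stopf("ddG table needs columns %s", paste(need, collapse = ", "))
  if (any(tab$wt == tab$mut)) stopf("ddG table contains wt == mut rows")
  if (!all(is.finite(tab$ddg))) stopf("non-finite ddG values")
  tab$id <- paste0(tab$wt, tab$position, tab$mut)
  if (anyDuplicated(tab$id)) stopf("duplicate mutation ids in ddG table")
  attr(tab, "source") <- source
  class(tab) <- c("ddg_table", "data.frame")
  tab
}

#' Stabilising sets of two ddG scans and their consensus intersection
#'
#' A mutation is stabilising iff ddg < threshold (strictly; negative =
#' stabilising).  Both tables must cover the same mutation universe.
#' Fractions are relative to the universe size, mirroring the reported
#' FoldX/Rosetta consensus bookkeeping (e.g. 1612 of 8398 = 19.2%).
#'
#' @param a,b `ddg_table` objects over the same mutation universe.
#' @param threshold stabilising threshold in kcal/mol (default 0).
#' @return list with `set_a`, `set_b`, `intersection` (mutation id
#'   vectors), `fractions` (named: a, b, both) and `n_universe`.
#' @export
stabilizing_consensus <- function(a, b, threshold = 0) {
  if (!setequal(a$id, b$id)) {
    miss_a <- setdiff(b$id, a$id); miss_b <- setdiff(a$id, b$id)
    stopf("mutation universes differ: %d ids missing from a (%s...), %d from b (%s...)",
          length(miss_a), paste(head(miss_a, 3), collapse = ","),
          length(miss_b), paste(head(miss_b, 3), collapse = ","))
  }
  set_a <- a$id[a$ddg < threshold]
  set_b <- b$id[b$ddg < threshold]
  inter <- intersect(set_a, set_b)
  n <- length(a$id)
  list(set_a = set_a, set_b = set_b, intersection = inter,
       fractions = c(a = length(set_a) / n, b = length(set_b) / n,
                     both = length(inter) / n),
       n_universe = n)
}

#' Column entropy of a multiple sequence alignment
#'
#' Shannon entropy H = -sum p_i ln p_i per column, in nats, over the
#' 21-symbol alphabet of the 20 amino acids plus the gap.  The maximum is
#' ln 21 = 3.04 (every symbol equally likely); 0 means a fully conserved
#' column.  Gap-only columns are single-symbol columns with H = 0.
#'
#' @param alignment aligned FASTA path, or a character vector of
#'   equal-length aligned sequences.
#' @return an `alignment_profile`: list with `entropy` (numeric per
#'   column), `counts` (21 x n_columns matrix) and `n_sequences`.
#' @export
column_entropy <- function(alignment) {
  seqs <- if (length(alignment) == 1L && file.exists(alignment))
    read_fasta(alignment) else alignment
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stopf("ragged alignment: sequence lengths %s", paste(unique(lens), collapse = ", "))
  alphabet <- c(.aa1, "-")
  mat <- do.call(rbind, strsplit(seqs, ""))
  mat[mat == "."] <- "-"
  bad <- setdiff(unique(as.vector(mat)), alphabet)
  if (length(bad))
    stopf("unknown alignment symbol(s): %s", paste(bad, collapse = ", "))
  counts <- apply(mat, 2, function(col) table(factor(col, levels = alphabet)))
  counts <- matrix(counts, nrow = length(alphabet),
                   dimnames = list(alphabet, NULL))
  entropy <- apply(counts, 2, function(k) {
    p <- k[k > 0] / sum(k)
    -sum(p * log(p)) + 0    # avoid IEEE negative zero for conserved columns
  })
  structure(list(entropy = as.numeric(entropy), counts = counts,
                 n_sequences = length(seqs)),
            class = "alignment_profile")
}

# FASTA reading via seqinr; sequences as a named character vector
read_fasta <- function(path) {
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          set.attributes = FALSE)
  if (length(s) == 0L) stopf("no FASTA records in %s", path)
  setNames(toupper(unlist(s)), names(s))
}

#' Consensus aggregation-prone regions from predictor masks
#'
#' A residue is selected iff at least `min_agree` of the per-residue
#' predictor masks mark it; maximal runs of selected residues become the
#' consensus intervals (the usual "3 of 4 predictors" rule).
#'
#' @param masks list of logical vectors of equal length (one per
#'   predictor), TRUE where the predictor calls an APR residue.
#' @param min_agree minimum number of agreeing predictors (default 3).
#' @return an `apr_set` with intervals named APR_start-end.
#' @export
apr_consensus <- function(masks, min_agree = 3L) {
  if (min_agree > length(masks))
    stopf("min_agree (%d) exceeds the number of masks (%d)",
          min_agree, length(masks))
  lens <- unique(vapply(masks, length, 1L))
  if (length(lens) != 1L) stopf("predictor masks differ in length")
  votes <- Reduce(`+`, lapply(masks, as.integer))
  sel <- votes >= min_agree
  if (!any(sel)) return(apr_set(list(), max_residue = lens))
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  intervals <- lapply(runs, function(k) c(starts[k], ends[k]))
  names(intervals) <- vapply(intervals, function(iv)
    sprintf("APR_%d-%d", iv[1], iv[2]), "")
  apr_set(intervals, max_residue = lens)
}
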