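# Distogram construction and the contact-map RMSD statistic (RMSD_map) used
# to score sequence-masked predictions, plus its success classifiers.

#' Construct a distogram object
#'
#' @param distances L x L symmetric matrix of representative inter-residue
#'   distances (Angstrom), zero diagonal.
#' @param chain_split number of receptor residues; rows/columns `1..chain_split`
#'   belong to the receptor, the rest to the peptide.
#' @param bins optional list with `edges` (bin bounds) and `probabilities`
#'   (L x L x B tensor) for bin-probability distograms.
#' @return object of class `Distogram`.
#' @export
distogram <- function(distances, chain_split, bins = NULL) {
  distances <- as.matrix(distances)
  L <- nrow(distances)
  stopifnot(ncol(distances) == L, chain_split > 0, chain_split < L)
  if (max(abs(distances - t(distances))) > 1e-6)
    stop("distance matrix must be symmetric within 1e-6")
  if (max(abs(diag(distances))) > 1e-6) stop("diagonal must be zero")
  structure(list(distances = distances, chain_split = as.integer(chain_split),
                 bins = bins), class = "Distogram")
}

#' Distogram from a complex structure
#'
#' Representative atom is C-beta, substituting C-alpha for glycine (the
#' AlphaFold distogram convention).
#'
#' @param complex a `ComplexStructure`.
#' @return a [distogram()] whose `chain_split` equals the receptor length.
#' @export
distogram_from_structure <- function(complex) {
  rec <- select_atoms(complex$receptor, "CB_proxy")
  pep <- select_atoms(complex$peptide, "CB_proxy")
  if (length(rec$skipped) || length(pep$skipped))
    stop("residue(s) missing both C-beta and C-alpha: ",
         paste(c(rec$skipped, pep$skipped), collapse = ", "))
  xyz <- rbind(rec$xyz, pep$xyz)
  d <- cross_dist(xyz, xyz)
  diag(d) <- 0
  d <- (d + t(d)) / 2                   # exact symmetry
  distogram(d, chain_split = complex$receptor$nres)
}

#' Collapse a per-pair bin distribution to a representative distance
#'
#' Probability-weighted mean of bin midpoints. When the final bin is open
#' (infinite upper edge, or one more probability than closed bins), its
#' midpoint is taken as its lower edge plus half the preceding bin width.
#'
#' @param probabilities non-negative bin probabilities summing to 1
#'   (tolerance 1e-4).
#' @param edges increasing bin bounds; length `B + 1` (the last may be
#'   `Inf`) or `B` (final bin open).
#' @return representative distance in Angstrom.
#' @export
collapse_bins <- function(probabilities, edges) {
  p <- as.numeric(probabilities)
  if (any(p < 0)) stop("negative bin probability")
  if (abs(sum(p) - 1) > 1e-4) stop("bin probabilities must sum to 1 (+-1e-4)")
  B <- length(p)
  if (length(edges) == B + 1 && is.finite(edges[B + 1])) {
    mids <- (edges[-(B + 1)] + edges[-1]) / 2
  } else {
    lower <- edges[seq_len(B)]
    if (length(edges) == B + 1) edges <- edges[seq_len(B)]
    mids <- c((lower[-B] + lower[-1]) / 2,
              lower[B] + (lower[B] - lower[B - 1]) / 2)
  }
  sum(p * mids)
}

#' Contact-map RMSD between native and predicted distograms
#'
#' Over the inter-chain residue pairs whose native representative distance
#' is at most `contact_cutoff`, computes
#' `sqrt((1/Nc) * sum (Dnat_ij - Dpred_ij)^2)` where `Nc` is the number of
#' qualifying pairs. The pair set is always defined on the native distogram.
#'
#' @param native,predicted `Distogram` objects with identical dimensions and
#'   chain split.
#' @param contact_cutoff native-distance cutoff (Angstrom) selecting the
#'   inter-chain contact pairs.
#' @return list of class `RmsdMapResult`: `value` (Angstrom), `n_contacts`,
#'   `pair_set` (2-column matrix of (i, j) indices).
#' @export
rmsd_map <- function(native, predicted, contact_cutoff = 12.0) {
  stopifnot(inherits(native, "Distogram"), inherits(predicted, "Distogram"))
  L <- nrow(native$distances)
  if (nrow(predicted$distances) != L ||
      native$chain_split != predicted$chain_split)
    stop("distograms must share dimensions and chain split")
  k <- native$chain_split
  block_n <- native$distances[seq_len(k), (k + 1):L, drop = FALSE]
  block_p <- predicted$distances[seq_len(k), (k + 1):L, drop = FALSE]
  sel <- which(block_n <= contact_cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0)
    stop("no native inter-chain contact under ", contact_cutoff, " Angstrom")
  diffs <- block_n[sel] - block_p[sel]
  structure(list(
    value = sqrt(mean(diffs^2)),
    n_contacts = nrow(sel),
    pair_set = cbind(i = sel[, 1], j = sel[, 2] + k)
  ), class = "RmsdMapResult")
}

#' Success classifiers for masked-peptide predictions
#'
#' `classify_masked_success()` calls a distogram comparison a docking success
#' when RMSD_map is strictly below 2.5 Angstrom; `classify_peptide_rmsd_success()`
#' calls a peptide backbone RMSD acceptable when strictly below 12 Angstrom.
#'
#' @param value non-negative RMSD_map or peptide RMSD (Angstrom).
#' @param threshold decision threshold (Angstrom).
#' @return logical.
#' @export
classify_masked_success <- function(value, threshold = 2.5) {
  if (any(value < 0)) stop("negative RMSD_map")
  value < threshold
}

#' @rdname classify_masked_success
#' @export
classify_peptide_rmsd_success <- function(value, threshold = 12.0) {
  if (any(value < 0)) stop("negative RMSD")
  value < threshold
}

#' Read / write the distogram TSV dialect
#'
#' A header line `# L=<n> chain_split=<k>` followed by tab-separated
#' `i j distance` triplets for the upper triangle.
#'
#' @param x a `Distogram` (write) or file path (read).
#' @param path output path.
#' @return `write_distogram()` returns `path` invisibly; `read_distogram()`
#'   a `Distogram`.
#' @export
write_distogram <- function(x, path) {
  stopifnot(inherits(x, "Distogram"))
  L <- nrow(x$distances)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# L=%d chain_split=%d", L, x$chain_split), con)
  ut <- which(upper.tri(x$distances), arr.ind = TRUE)
  writeLines(sprintf("%d\t%d\t%.6f", ut[, 1], ut[, 2],
                     x$distances[ut]), con)
  invisible(path)
}

#' @rdname write_distogram
#' @export
read_distogram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- regmatches(lines[1], regexec("L=(\\d+) chain_split=(\\d+)", lines[1]))[[1]]
  if (length(hdr) != 3) stop("malformed distogram header")
  L <- as.integer(hdr[2]); k <- as.integer(hdr[3])
  body <- utils::read.table(text = lines[-1], sep = "\t",
                            col.names = c("i", "j", "d"))
  m <- matrix(0, L, L)
  m[cbind(body$i, body$j)] <- body$d
  m[cbind(body$j, body$i)] <- body$d
  distogram(m, k)
}
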