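# Model-confidence summaries correlated with docking accuracy: ranking
# confidence (ipTM+pTM), inter-chain PAE mean (iPAE), and pDockQ.

#' Construct a confidence record
#'
#' Holds the confidence outputs of an AF-style predictor for one complex.
#'
#' @param ptm,iptm global and interface predicted TM-scores in \[0, 1\].
#' @param plddt per-residue confidence, 0-100, length L (receptor then
#'   peptide).
#' @param pae L x L predicted aligned error matrix, Angstrom, non-negative.
#' @param chain_split number of receptor residues.
#' @return list of class `ConfidenceRecord`.
#' @export
confidence_record <- function(ptm, iptm, plddt, pae, chain_split) {
  pae <- as.matrix(pae)
  L <- length(plddt)
  stopifnot(ptm >= 0, ptm <= 1, iptm >= 0, iptm <= 1,
            nrow(pae) == L, ncol(pae) == L, all(pae >= 0),
            chain_split >= 1, chain_split < L)
  structure(list(ptm = ptm, iptm = iptm, plddt = as.numeric(plddt),
                 pae = pae, chain_split = as.integer(chain_split)),
            class = "ConfidenceRecord")
}

#' Read a confidence record from JSON
#'
#' Expects the JSON layout emitted by AF-style pipelines: scalar `ptm` and
#' `iptm`, a `plddt` array and a `pae` matrix, plus `chain_split` (or a
#' `chain_lengths` array whose first element is the receptor length).
#'
#' @param path JSON file path.
#' @return a [confidence_record()].
#' @export
read_confidence_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  split <- x$chain_split %||% x$chain_lengths[1]
  confidence_record(x$ptm, x$iptm, x$plddt, x$pae, split)
}

#' Ranking confidence (ipTM+pTM)
#'
#' Weighted combination `w1*iptm + w2*ptm`; the default weights (0.8, 0.2)
#' are the AF2-Multimer ranking convention, reported under the label
#' "ipTM+pTM". Use `weights = c(1, 1)` for the literal sum.
#'
#' @param iptm,ptm values in \[0, 1\].
#' @param weights length-2 numeric `(w_iptm, w_ptm)`.
#' @return the combined confidence.
#' @export
ranking_confidence <- function(iptm, ptm, weights = c(0.8, 0.2)) {
  if (any(iptm < 0 | iptm > 1 | ptm < 0 | ptm > 1))
    stop("iptm and ptm must lie in [0, 1]")
  weights[1] * iptm + weights[2] * ptm
}

#' Inter-chain PAE mean (iPAE)
#'
#' Mean predicted aligned error over all ordered residue pairs with the two
#' residues on different chains (both off-diagonal blocks).
#'
#' @param record a `ConfidenceRecord`, or a PAE matrix if `chain_split` is
#'   given.
#' @param chain_split receptor length when `record` is a bare matrix.
#' @return iPAE in Angstrom.
#' @export
interchain_pae <- function(record, chain_split = NULL) {
  if (inherits(record, "ConfidenceRecord")) {
    pae <- record$pae; k <- record$chain_split
  } else {
    pae <- as.matrix(record); k <- chain_split
    if (is.null(k)) stop("chain_split required for a bare PAE matrix")
  }
  L <- nrow(pae)
  if (k < 1 || k >= L) stop("degenerate chain split")
  ri <- seq_len(k); pi <- (k + 1):L
  mean(c(pae[ri, pi], pae[pi, ri]))
}

#' pDockQ sigmoid confidence score
#'
#' `pDockQ = b + L / (1 + exp(-k*(x - x0)))` with
#' `x = mean interface pLDDT * ln(n_interface_contacts)` and the published
#' constants L = 0.724, x0 = 152.611, k = 0.052, b = 0.018.
#'
#' @param mean_interface_plddt mean pLDDT (0-100) over interface residues.
#' @param n_interface_contacts number of interface residue contacts (>= 1).
#' @param L,x0,k,b sigmoid constants.
#' @return pDockQ in the open interval (b, L + b).
#' @export
pdockq <- function(mean_interface_plddt, n_interface_contacts,
                   L = 0.724, x0 = 152.611, k = 0.052, b = 0.018) {
  if (any(n_interface_contacts < 1)) stop("need at least one interface contact")
  x <- mean_interface_plddt * log(n_interface_contacts)
  b + L / (1 + exp(-k * (x - x0)))
}

#' pDockQ from a predicted structure and its confidence record
#'
#' Interface contacts are residue pairs under the 5-Angstrom heavy-atom rule
#' on the predicted structure; interface pLDDT is the mean over the residues
#' participating in those pairs (both chains, pLDDT indexed over the
#' concatenated residues).
#'
#' @param predicted a `ComplexStructure` (the prediction).
#' @param record a `ConfidenceRecord` for the same complex.
#' @param contact_cutoff heavy-atom contact cutoff, Angstrom.
#' @return pDockQ value.
#' @export
pdockq_from_structure <- function(predicted, record, contact_cutoff = 5.0) {
  ct <- native_contacts(predicted, contact_cutoff)
  n <- nrow(ct$pairs)
  if (n == 0) stop("prediction has no interface contacts")
  k <- record$chain_split
  res_idx <- unique(c(ct$pairs[, 1], ct$pairs[, 2] + k))
  pdockq(mean(record$plddt[res_idx]), n)
}

#' Summarize a confidence record
#'
#' @param record a `ConfidenceRecord`.
#' @param predicted optional predicted `ComplexStructure` enabling pDockQ.
#' @param weights passed to [ranking_confidence()].
#' @return list of class `ConfidenceSummary`: `ranking_confidence`, `ipae`,
#'   `pdockq` (NA when no structure is supplied).
#' @export
confidence_summary <- function(record, predicted = NULL, weights = c(0.8, 0.2)) {
  structure(list(
    ranking_confidence = ranking_confidence(record$iptm, record$ptm, weights),
    ipae = interchain_pae(record),
    pdockq = if (is.null(predicted)) NA_real_
             else pdockq_from_structure(predicted, record)
  ), class = "ConfidenceSummary")
}
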