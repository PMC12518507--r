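# Docking accuracy metrics: Kabsch superposition, native contacts, DockQ and
# its quality categories, peptide RMSD after receptor alignment, the
# atomic-accuracy criterion, TM-score, and a simplified dihedral-rule
# secondary-structure assignment.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mov` onto `ref` over corresponding rows.
#' The returned transform uses the row-vector convention:
#' `fitted = mov %*% rotation + translation` (rows are points).
#'
#' @param ref,mov n x 3 coordinate matrices, n >= 3, corresponding by row.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   `rmsd` (post-fit, Angstrom) and `collinear` (TRUE when the reference
#'   point cloud is degenerate and the rotation is not unique).
#' @export
superpose_kabsch <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  stopifnot(ncol(ref) == 3, ncol(mov) == 3, nrow(ref) == nrow(mov))
  if (nrow(ref) < 3) stop("need at least 3 points to superpose")
  cr <- colMeans(ref); cm <- colMeans(mov)
  r0 <- sweep(ref, 2, cr); m0 <- sweep(mov, 2, cm)
  h <- crossprod(m0, r0)               # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- m0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - r0)^2)))
  # degenerate (collinear) clouds leave the smallest singular values ~0
  collinear <- sum(svd(r0, nu = 0, nv = 0)$d > 1e-8 * max(1, nrow(ref))) < 2
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot),
       rmsd = rmsd, collinear = collinear)
}

apply_superposition <- function(xyz, sup) {
  as.matrix(xyz) %*% sup$rotation +
    matrix(sup$translation, nrow(xyz), 3, byrow = TRUE)
}

chain_heavy <- function(chain) select_atoms(chain, "heavy")

#' Native inter-chain residue contacts
#'
#' A (receptor residue, peptide residue) pair is a contact when any
#' heavy-atom inter-chain distance is below `cutoff` (5 Angstrom by
#' DockQ convention).
#'
#' @param complex a `ComplexStructure`.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return list of class `ContactSet` with `pairs` (2-column matrix of
#'   residue `seq_index` values, receptor then peptide) and `cutoff`.
#' @export
native_contacts <- function(complex, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  rec <- chain_heavy(complex$receptor)
  pep <- chain_heavy(complex$peptide)
  d <- cross_dist(rec$xyz, pep$xyz)
  hit <- which(d < cutoff, arr.ind = TRUE)
  pairs <- unique(cbind(receptor = rec$residue[hit[, 1]],
                        peptide = pep$residue[hit[, 2]]))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(pairs = pairs, cutoff = cutoff), class = "ContactSet")
}

contact_key <- function(pairs) paste(pairs[, 1], pairs[, 2])

# Residues of both chains with any heavy atom within `cutoff` of the other
# chain (the DockQ 10-A interface-residue rule), computed on the native.
interface_residue_sets <- function(complex, cutoff = 10.0) {
  rec <- chain_heavy(complex$receptor)
  pep <- chain_heavy(complex$peptide)
  d <- cross_dist(rec$xyz, pep$xyz)
  hit <- d < cutoff
  list(receptor = sort(unique(rec$residue[rowSums(hit) > 0])),
       peptide = sort(unique(pep$residue[colSums(hit) > 0])))
}

# Matched coordinate pairs for the same residues/atom names in two complexes.
# sel_fun extracts a selection from a chain; residues restricts by seq_index.
matched_coords <- function(nat_chain, prd_chain, mode, residues = NULL) {
  a <- select_atoms(nat_chain, mode)
  b <- select_atoms(prd_chain, mode)
  key_a <- paste(a$residue, a$atom)
  key_b <- paste(b$residue, b$atom)
  common <- intersect(key_a, key_b)
  if (!is.null(residues)) {
    keep_res <- a$residue[match(common, key_a)] %in% residues
    common <- common[keep_res]
  }
  list(native = a$xyz[match(common, key_a), , drop = FALSE],
       predicted = b$xyz[match(common, key_b), , drop = FALSE])
}

check_correspondence <- function(native, predicted) {
  if (native$receptor$nres != predicted$receptor$nres ||
      native$peptide$nres != predicted$peptide$nres)
    stop("native and predicted complexes must have equal residue counts per chain")
}

#' DockQ docking-quality score
#'
#' Composite score in \[0, 1\] combining the fraction of recovered native
#' contacts (Fnat), the interface backbone RMSD (iRMSD) and the
#' ligand/peptide backbone RMSD after receptor superposition (LRMSD):
#' `DockQ = (Fnat + 1/(1+(iRMSD/1.5)^2) + 1/(1+(LRMSD/8.5)^2)) / 3`.
#' 1 represents perfect recovery of the native interface.
#'
#' @param native,predicted `ComplexStructure` objects with residue
#'   correspondence by identical order (equal residue counts per chain).
#' @param contact_cutoff heavy-atom contact cutoff (Angstrom) for Fnat.
#' @param interface_cutoff heavy-atom cutoff defining native interface
#'   residues for iRMSD.
#' @param ca_only use C-alpha atoms instead of the 4-atom backbone for the
#'   RMSD terms.
#' @return list of class `DockQResult`: `fnat`, `irmsd`, `lrmsd`, `score`,
#'   `category` (see [categorize_dockq()]).
#' @export
dockq <- function(native, predicted, contact_cutoff = 5.0,
                  interface_cutoff = 10.0, ca_only = FALSE) {
  check_correspondence(native, predicted)
  mode <- if (ca_only) "CA" else "backbone"

  nat_ct <- native_contacts(native, contact_cutoff)
  if (nrow(nat_ct$pairs) == 0)
    stop("no native inter-chain contacts under ", contact_cutoff,
         " Angstrom; DockQ undefined")
  prd_ct <- native_contacts(predicted, contact_cutoff)
  fnat <- mean(contact_key(nat_ct$pairs) %in% contact_key(prd_ct$pairs))

  ifc <- interface_residue_sets(native, interface_cutoff)
  rec_m <- matched_coords(native$receptor, predicted$receptor, mode, ifc$receptor)
  pep_m <- matched_coords(native$peptide, predicted$peptide, mode, ifc$peptide)
  nat_i <- rbind(rec_m$native, pep_m$native)
  prd_i <- rbind(rec_m$predicted, pep_m$predicted)
  irmsd <- superpose_kabsch(nat_i, prd_i)$rmsd

  rec_all <- matched_coords(native$receptor, predicted$receptor, mode)
  sup <- superpose_kabsch(rec_all$native, rec_all$predicted)
  pep_all <- matched_coords(native$peptide, predicted$peptide, mode)
  lrmsd <- rmsd_coords(pep_all$native, apply_superposition(pep_all$predicted, sup))

  score <- (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
  structure(list(fnat = fnat, irmsd = irmsd, lrmsd = lrmsd, score = score,
                 category = categorize_dockq(score)),
            class = "DockQResult")
}

#' Map a DockQ score to its quality category
#'
#' Thresholds follow the CAPRI-style bands: poor below 0.23, acceptable up
#' to 0.49, medium up to 0.80, high above 0.80.
#'
#' @param score numeric in \[0, 1\].
#' @return one of `"poor"`, `"acceptable"`, `"medium"`, `"high"`.
#' @export
categorize_dockq <- function(score) {
  if (any(score < 0 | score > 1)) stop("DockQ score must lie in [0, 1]")
  vapply(score, function(s) {
    if (s < 0.23) "poor"
    else if (s <= 0.49) "acceptable"
    else if (s <= 0.80) "medium"
    else "high"
  }, character(1))
}

#' Peptide RMSD after aligning the receptor chains
#'
#' Superposes the predicted receptor backbone onto the native receptor
#' backbone and reports `sqrt((1/N) * sum |pred_i - nat_i|^2)` over the N
#' peptide backbone atoms in that frame.
#'
#' @inheritParams dockq
#' @param atoms `"backbone"` (N, CA, C, O) or `"CA"`.
#' @return RMSD in Angstrom.
#' @export
peptide_rmsd_after_protein_alignment <- function(native, predicted,
                                                 atoms = c("backbone", "CA")) {
  atoms <- match.arg(atoms)
  check_correspondence(native, predicted)
  rec <- matched_coords(native$receptor, predicted$receptor, atoms)
  if (nrow(rec$native) == 0) stop("no shared receptor backbone atoms")
  sup <- superpose_kabsch(rec$native, rec$predicted)
  pep <- matched_coords(native$peptide, predicted$peptide, atoms)
  rmsd_coords(pep$native, apply_superposition(pep$predicted, sup))
}

#' Atomic-accuracy criterion
#'
#' A prediction is atomically accurate when it recovers more than 90% of
#' native contacts, has no inter-chain clash (heavy-atom distance below
#' `clash_cutoff`), peptide all-atom RMSD below 2 Angstrom (receptor-backbone
#' frame) and interface all-atom RMSD below 3 Angstrom (interface-heavy-atom
#' frame).
#'
#' @inheritParams dockq
#' @param clash_cutoff inter-chain heavy-atom distance defining a clash.
#' @return list of class `AtomicAccuracyResult`: `fnat`, `clash_count`,
#'   `peptide_allatom_rmsd`, `interface_allatom_rmsd`, `passed`.
#' @export
atomic_accuracy <- function(native, predicted, contact_cutoff = 5.0,
                            interface_cutoff = 10.0, clash_cutoff = 2.0) {
  check_correspondence(native, predicted)
  nat_ct <- native_contacts(native, contact_cutoff)
  if (nrow(nat_ct$pairs) == 0) stop("no native inter-chain contacts")
  prd_ct <- native_contacts(predicted, contact_cutoff)
  fnat <- mean(contact_key(nat_ct$pairs) %in% contact_key(prd_ct$pairs))

  rec_p <- chain_heavy(predicted$receptor)
  pep_p <- chain_heavy(predicted$peptide)
  clash_count <- sum(cross_dist(rec_p$xyz, pep_p$xyz) < clash_cutoff)

  rec_bb <- matched_coords(native$receptor, predicted$receptor, "backbone")
  sup <- superpose_kabsch(rec_bb$native, rec_bb$predicted)
  pep_all <- matched_coords(native$peptide, predicted$peptide, "heavy")
  pep_rmsd <- rmsd_coords(pep_all$native,
                          apply_superposition(pep_all$predicted, sup))

  ifc <- interface_residue_sets(native, interface_cutoff)
  rec_i <- matched_coords(native$receptor, predicted$receptor, "heavy", ifc$receptor)
  pep_i <- matched_coords(native$peptide, predicted$peptide, "heavy", ifc$peptide)
  iface_rmsd <- superpose_kabsch(rbind(rec_i$native, pep_i$native),
                                 rbind(rec_i$predicted, pep_i$predicted))$rmsd

  structure(list(
    fnat = fnat, clash_count = clash_count,
    peptide_allatom_rmsd = pep_rmsd, interface_allatom_rmsd = iface_rmsd,
    passed = fnat > 0.9 && clash_count == 0 && pep_rmsd < 2 && iface_rmsd < 3
  ), class = "AtomicAccuracyResult")
}

#' TM-score between two conformations of the same chain
#'
#' Length-normalized structural similarity in \[0, 1\]:
#' `TM = max over superpositions of (1/L) * sum 1/(1 + (d_i/d0)^2)` with
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8` floored at 0.5. The maximum is sought
#' by the standard iterative scheme: fragment seeds of length L, L/2 and 4
#' starting at every 4th residue, each refined for up to 20 iterations with
#' a growing distance-inclusion cutoff.
#'
#' @param native_chain,predicted_chain `Chain` objects of equal length
#'   (same protein, correspondence by residue order).
#' @return TM-score in \[0, 1\].
#' @export
tm_score <- function(native_chain, predicted_chain) {
  nat <- select_atoms(native_chain, "CA")
  prd <- select_atoms(predicted_chain, "CA")
  common <- intersect(nat$residue, prd$residue)
  L <- length(common)
  if (L < 3) stop("need at least 3 corresponding C-alpha atoms")
  a <- nat$xyz[match(common, nat$residue), , drop = FALSE]
  b <- prd$xyz[match(common, prd$residue), , drop = FALSE]
  d0 <- max(0.5, 1.24 * cbrt(L - 15) - 1.8)

  score_for <- function(sup) {
    d <- sqrt(rowSums((a - apply_superposition(b, sup))^2))
    list(score = mean(1 / (1 + (d / d0)^2)), d = d)
  }
  best <- 0
  frag_lens <- unique(pmax(4, pmin(L, c(L, floor(L / 2), 4))))
  for (fl in frag_lens) {
    starts <- seq(1, L - fl + 1, by = 4)
    for (s in starts) {
      idx <- s:(s + fl - 1)
      if (length(idx) < 3) next
      sup <- superpose_kabsch(a[idx, , drop = FALSE], b[idx, , drop = FALSE])
      sc <- score_for(sup)
      best <- max(best, sc$score)
      for (it in seq_len(20)) {
        cut <- d0 + 1
        incl <- which(sc$d < cut)
        while (length(incl) < 3) {        # widen until enough atoms
          cut <- cut + 1
          incl <- which(sc$d < cut)
        }
        sup2 <- superpose_kabsch(a[incl, , drop = FALSE], b[incl, , drop = FALSE])
        sc2 <- score_for(sup2)
        best <- max(best, sc2$score)
        if (identical(incl, which(sc2$d < cut))) { sc <- sc2; break }
        sc <- sc2
      }
    }
  }
  best
}

#' Simplified secondary-structure assignment from backbone dihedrals
#'
#' A dihedral-region stand-in for DSSP: residue labelled `H` when
#' phi in (-100, -30) and psi in (-80, -5) within a run of at least 4,
#' `E` when phi in (-170, -40) and psi in (90, 180] within a run of at
#' least 3, else `L`. Chain termini (undefined phi or psi) are `L`.
#'
#' @param chain a `Chain` with backbone atoms for consecutive residues.
#' @return list of class `SSAssignment` with `labels`, a string over
#'   `{H, E, L}` of length equal to the residue count.
#' @export
assign_secondary_structure <- function(chain) {
  n <- chain$nres
  ang <- backbone_dihedrals(chain)
  is_h <- !is.na(ang$phi) & !is.na(ang$psi) &
    ang$phi > -100 & ang$phi < -30 & ang$psi > -80 & ang$psi < -5
  is_e <- !is.na(ang$phi) & !is.na(ang$psi) &
    ang$phi > -170 & ang$phi < -40 & ang$psi > 90 & ang$psi <= 180
  lab <- rep("L", n)
  lab[run_filter(is_h, 4)] <- "H"
  lab[run_filter(is_e, 3) & lab == "L"] <- "E"
  structure(list(labels = paste(lab, collapse = "")), class = "SSAssignment")
}

# Keep only positions inside runs of TRUE of length >= k.
run_filter <- function(flag, k) {
  r <- rle(flag)
  r$values <- r$values & r$lengths >= k
  inverse.rle(r)
}

# phi/psi (degrees) per residue; NA where undefined (termini, missing atoms).
backbone_dihedrals <- function(chain) {
  n <- chain$nres
  get <- function(ri, nm) {
    a <- chain$atoms
    idx <- which(a$seq_index == ri & a$atom == nm)
    if (!length(idx)) return(NULL)
    as.numeric(a[idx[1], c("x", "y", "z")])
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- get(i, "N"); CAi <- get(i, "CA"); Ci <- get(i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1) {
      Cprev <- get(i - 1, "C")
      if (!is.null(Cprev)) phi[i] <- dihedral_angle(Cprev, Ni, CAi, Ci)
    }
    if (i < n) {
      Nnext <- get(i + 1, "N")
      if (!is.null(Nnext)) psi[i] <- dihedral_angle(Ni, CAi, Ci, Nnext)
    }
  }
  list(phi = phi, psi = psi)
}

#' @export
print.DockQResult <- function(x, ...) {
  cat(sprintf("DockQ %.3f (%s): Fnat %.3f, iRMSD %.2f A, LRMSD %.2f A\n",
              x$score, x$category, x$fnat, x$irmsd, x$lrmsd))
  invisible(x)
}
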