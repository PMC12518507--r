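# Binding-site definition, dated-library binding-site-match search, site
# overlap, and conservation/hydrophobicity site statistics.

#' Receptor residues at the peptide interface
#'
#' A receptor residue belongs to the binding site when any of its heavy
#' atoms lies within `cutoff` of any peptide heavy atom (consistent with the
#' Fnat contact convention).
#'
#' @param complex a `ComplexStructure`.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @return list of class `BindingSite` with `residues` (sorted receptor
#'   `seq_index` values) and `cutoff`.
#' @export
interface_residues <- function(complex, cutoff = 5.0) {
  rec <- select_atoms(complex$receptor, "heavy")
  pep <- select_atoms(complex$peptide, "heavy")
  d <- cross_dist(rec$xyz, pep$xyz)
  res <- sort(unique(rec$residue[rowSums(d < cutoff) > 0]))
  structure(list(residues = res, cutoff = cutoff), class = "BindingSite")
}

#' Jaccard overlap between two binding sites
#'
#' Sites are declared "the same site" when the Jaccard index is at least
#' `same_site_threshold` (default 0.25).
#'
#' @param site_a,site_b `BindingSite` objects on the same receptor indexing.
#' @param same_site_threshold Jaccard threshold for the same-site call.
#' @return the Jaccard index, with logical attribute `same_site`.
#' @export
site_overlap <- function(site_a, site_b, same_site_threshold = 0.25) {
  a <- site_a$residues; b <- site_b$residues
  if (!length(a) && !length(b)) stop("both sites are empty")
  j <- length(intersect(a, b)) / length(union(a, b))
  structure(j, same_site = j >= same_site_threshold)
}

#' Conservation and hydrophobicity statistics of a binding site
#'
#' Means of the per-column conservation score and of the residue
#' hydrophobicity over the site versus its complement on the receptor.
#'
#' @param site a `BindingSite`.
#' @param profile a `ConservationProfile` whose length equals the receptor
#'   length.
#' @param sequence receptor 1-letter sequence (string).
#' @param scale hydrophobicity table (see [mean_hydrophobicity()]).
#' @return list of class `SiteStats`: `mean_jsd_site`, `mean_jsd_nonsite`,
#'   `mean_hydrophobicity_site`, `mean_hydrophobicity_nonsite`.
#' @export
site_profile_stats <- function(site, profile, sequence, scale = KYTE_DOOLITTLE) {
  n <- nchar(sequence)
  if (length(profile$jsd) != n)
    stop("profile length != receptor length")
  s <- site$residues
  ns <- setdiff(seq_len(n), s)
  if (!length(s) || !length(ns)) stop("site or complement is empty")
  ch <- strsplit(sequence, "")[[1]]
  structure(list(
    mean_jsd_site = mean(profile$jsd[s]),
    mean_jsd_nonsite = mean(profile$jsd[ns]),
    mean_hydrophobicity_site = as.numeric(mean_hydrophobicity(ch[s], scale)),
    mean_hydrophobicity_nonsite = as.numeric(mean_hydrophobicity(ch[ns], scale))
  ), class = "SiteStats")
}

#' Create a dated match-library entry
#'
#' @param complex a `ComplexStructure`.
#' @param release_date entry release date (required).
#' @param entry_id identifier; defaults to the complex id.
#' @return list of class `MatchLibraryEntry`.
#' @export
match_library_entry <- function(complex, release_date, entry_id = complex$id) {
  release_date <- as.Date(release_date)
  if (is.na(release_date)) stop("library entries must have a known date")
  structure(list(complex = complex, release_date = release_date,
                 entry_id = entry_id),
            class = "MatchLibraryEntry")
}

# Global pairwise sequence identity in [0, 1] (Biostrings global alignment,
# identity over the alignment length including gaps).
global_seq_identity <- function(seq_a, seq_b) {
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  p <- Biostrings::pid(aln, type = "PID1") / 100
  if (is.na(p)) 0 else p
}

# Best contiguous-window C-alpha correspondence between two coordinate sets
# of possibly different lengths: slide the shorter along the longer, return
# the offset pair minimizing RMSD after Kabsch fit (for superposition) or
# without refit (rmsd_only, fixed frame).
best_window_rmsd <- function(a, b, refit = TRUE) {
  na <- nrow(a); nb <- nrow(b)
  w <- min(na, nb)
  best <- list(rmsd = Inf)
  for (sa in seq_len(na - w + 1)) {
    for (sb in seq_len(nb - w + 1)) {
      aa <- a[sa:(sa + w - 1), , drop = FALSE]
      bb <- b[sb:(sb + w - 1), , drop = FALSE]
      r <- if (refit) superpose_kabsch(aa, bb)$rmsd else rmsd_coords(aa, bb)
      if (r < best$rmsd) best <- list(rmsd = r, a_idx = sa:(sa + w - 1),
                                      b_idx = sb:(sb + w - 1))
    }
  }
  best
}

ca_coords <- function(chain) select_atoms(chain, "CA")$xyz

# TM-score of two receptors allowing a length mismatch via the best
# contiguous-window correspondence.
receptor_tm <- function(query_rec, entry_rec) {
  if (query_rec$nres == entry_rec$nres) return(tm_score(query_rec, entry_rec))
  a <- ca_coords(query_rec); b <- ca_coords(entry_rec)
  win <- best_window_rmsd(a, b)
  qa <- subset_chain_ca(query_rec, win$a_idx)
  qb <- subset_chain_ca(entry_rec, win$b_idx)
  tm_score(qa, qb)
}

# Minimal CA-only chain restricted to a residue window (internal).
subset_chain_ca <- function(chain, residues) {
  a <- chain$atoms
  keep <- a$seq_index %in% residues & a$atom == "CA"
  df <- a[keep, c("resno", "insert", "resname", "atom", "element",
                  "x", "y", "z", "occupancy", "altloc")]
  ch <- chain_from_atoms(chain$id, chain$role, df)
  ch
}

#' Search a dated library for binding-site matches
#'
#' Implements the training-set overlap test: (1) entries released on or
#' after `cutoff_date` are dropped; (2) an entry's receptor must be
#' homologous to the query receptor, by global sequence identity at least
#' `seq_identity_threshold` or receptor-receptor TM-score at least
#' `tm_threshold` (either arm suffices); (3) the entry receptor is
#' superposed onto the query receptor (structure-based C-alpha fit for
#' structural hits, sequence-correspondence Kabsch for sequence-only hits);
#' (4) the C-alpha RMSD between the query peptide and the entry's bound
#' partner is computed in that fixed frame, using the best contiguous-window
#' correspondence when lengths differ (no re-superposition); (5) the entry
#' is a binding-site match when that partner RMSD is below
#' `partner_rmsd_threshold`.
#'
#' @param query a `ComplexStructure` (receptor with at least 3 C-alpha).
#' @param library list of [match_library_entry()] objects.
#' @param cutoff_date training-data cutoff; entries dated on/after it are
#'   excluded.
#' @param partner_rmsd_threshold match threshold, Angstrom (default 10).
#' @param seq_identity_threshold,tm_threshold homology thresholds.
#' @param use_sequence,use_structure enable/disable the two homology arms.
#' @return list of class `MatchResult`: `n_matches`, `matches` (data.frame
#'   `entry_id`, `partner_rmsd`, `evidence`), `n_candidates_after_date`.
#' @export
find_binding_site_matches <- function(query, library, cutoff_date,
                                      partner_rmsd_threshold = 10.0,
                                      seq_identity_threshold = 0.30,
                                      tm_threshold = 0.5,
                                      use_sequence = TRUE,
                                      use_structure = TRUE) {
  cutoff_date <- as.Date(cutoff_date)
  q_ca <- ca_coords(query$receptor)
  if (nrow(q_ca) < 3) stop("query receptor needs at least 3 C-alpha atoms")
  q_pep <- ca_coords(query$peptide)
  q_seq <- chain_sequence(query$receptor)

  dated <- Filter(function(e) e$release_date < cutoff_date, library)
  out <- data.frame(entry_id = character(0), partner_rmsd = numeric(0),
                    evidence = character(0), stringsAsFactors = FALSE)
  for (e in dated) {
    e_rec <- e$complex$receptor
    seq_hit <- use_sequence &&
      global_seq_identity(q_seq, chain_sequence(e_rec)) >= seq_identity_threshold
    str_hit <- use_structure && receptor_tm(query$receptor, e_rec) >= tm_threshold
    if (!seq_hit && !str_hit) next

    e_ca <- ca_coords(e_rec)
    if (str_hit) {
      if (nrow(q_ca) == nrow(e_ca)) {
        sup <- superpose_kabsch(q_ca, e_ca)
      } else {
        win <- best_window_rmsd(q_ca, e_ca)
        sup <- superpose_kabsch(q_ca[win$a_idx, , drop = FALSE],
                                e_ca[win$b_idx, , drop = FALSE])
      }
    } else {
      corr <- sequence_correspondence(q_seq, chain_sequence(e_rec))
      if (nrow(corr) < 3) next
      sup <- superpose_kabsch(q_ca[corr[, 1], , drop = FALSE],
                              e_ca[corr[, 2], , drop = FALSE])
    }
    partner <- apply_superposition(ca_coords(e$complex$peptide), sup)
    prmsd <- if (nrow(partner) == nrow(q_pep)) rmsd_coords(q_pep, partner)
             else best_window_rmsd(q_pep, partner, refit = FALSE)$rmsd
    if (prmsd < partner_rmsd_threshold) {
      ev <- if (seq_hit && str_hit) "both" else if (seq_hit) "sequence" else "structure"
      out <- rbind(out, data.frame(entry_id = e$entry_id, partner_rmsd = prmsd,
                                   evidence = ev, stringsAsFactors = FALSE))
    }
  }
  structure(list(n_matches = nrow(out), matches = out,
                 n_candidates_after_date = length(dated)),
            class = "MatchResult")
}

# Aligned (query_pos, subject_pos) index pairs from a global alignment.
sequence_correspondence <- function(seq_a, seq_b) {
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  res <- matrix(integer(0), ncol = 2)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (ps[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && ps[k] != "-") res <- rbind(res, c(ia, ib))
  }
  res
}

#' Read a match-library manifest
#'
#' TSV with columns `entry_id`, `path`, `receptor_chain`, `partner_chain`,
#' `release_date` (ISO-8601); each file is loaded via [read_structure()].
#'
#' @param path manifest file path.
#' @return list of `MatchLibraryEntry` objects.
#' @export
read_match_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("entry_id", "path", "receptor_chain", "partner_chain", "release_date")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    cx <- read_structure(tab$path[i], tab$receptor_chain[i], tab$partner_chain[i],
                         id = tab$entry_id[i])
    match_library_entry(cx, tab$release_date[i], tab$entry_id[i])
  })
}
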