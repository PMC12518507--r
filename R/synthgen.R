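# Seeded generators for every input class the pipeline consumes: ideal-
# geometry toy complexes, controlled-error "predictions", coevolving MSAs
# with species tags, and dated match libraries with planted homologs.
# All generators are pure functions of their arguments (seed included).

IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.53,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_c_ca_cb = 110.1, d_n_c_ca_cb = 122.6
)

DIHEDRALS <- list(helix = c(phi = -60, psi = -45),
                  strand = c(phi = -120, psi = 135))

# Ideal backbone (N, CA, C, O + CB stub except Gly) built by sequential
# internal-coordinate placement with constant phi/psi.
build_ideal_chain <- function(chain_id, role, sequence, phi, psi) {
  g <- IDEAL_GEOM
  n <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  Ns <- CAs <- Cs <- vector("list", n)
  Ns[[1]] <- c(0, 0, 0)
  CAs[[1]] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  Cs[[1]] <- CAs[[1]] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    Ns[[i]] <- place_atom(Ns[[i - 1]], CAs[[i - 1]], Cs[[i - 1]],
                          g$b_c_n, g$a_ca_c_n, psi)
    CAs[[i]] <- place_atom(CAs[[i - 1]], Cs[[i - 1]], Ns[[i]],
                           g$b_n_ca, g$a_c_n_ca, 180)
    Cs[[i]] <- place_atom(Cs[[i - 1]], Ns[[i]], CAs[[i]],
                          g$b_ca_c, g$a_n_ca_c, phi)
  }
  rows <- list()
  for (i in seq_len(n)) {
    O <- place_atom(Ns[[i]], CAs[[i]], Cs[[i]], g$b_c_o, g$a_ca_c_o, psi - 180)
    atoms <- rbind(
      data.frame(atom = "N", element = "N", x = Ns[[i]][1], y = Ns[[i]][2], z = Ns[[i]][3]),
      data.frame(atom = "CA", element = "C", x = CAs[[i]][1], y = CAs[[i]][2], z = CAs[[i]][3]),
      data.frame(atom = "C", element = "C", x = Cs[[i]][1], y = Cs[[i]][2], z = Cs[[i]][3]),
      data.frame(atom = "O", element = "O", x = O[1], y = O[2], z = O[3])
    )
    if (aa[i] != "G") {
      CB <- place_atom(Ns[[i]], Cs[[i]], CAs[[i]], g$b_ca_cb, g$a_c_ca_cb,
                       g$d_n_c_ca_cb)
      atoms <- rbind(atoms, data.frame(atom = "CB", element = "C",
                                       x = CB[1], y = CB[2], z = CB[3]))
    }
    atoms$resno <- i
    atoms$insert <- ""
    atoms$resname <- AA_123[aa[i]]
    atoms$occupancy <- 1
    atoms$altloc <- ""
    rows[[i]] <- atoms
  }
  df <- do.call(rbind, rows)
  chain_from_atoms(chain_id, role,
                   df[, c("resno", "insert", "resname", "atom", "element",
                          "x", "y", "z", "occupancy", "altloc")])
}

# Rotate a chain so its CA principal axis lies on x and the CA centroid at
# the origin; returns the chain plus the frame used.
canonicalize_chain <- function(chain) {
  ca <- select_atoms(chain, "CA")$xyz
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  rot <- sv$v
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  transform_chain(chain, rotation = rot, translation = -as.numeric(cen %*% rot))
}

min_interchain_dist <- function(rec_xyz, pep_xyz) min(cross_dist(rec_xyz, pep_xyz))

random_sequence <- function(n) paste(sample(AA1, n, replace = TRUE), collapse = "")

#' Generate a synthetic protein-peptide complex
#'
#' Builds ideal-geometry backbones (standard bond lengths and angles,
#' helical or extended dihedrals) with C-beta stubs, and docks the peptide
#' against the receptor face so that at least `min_contacts` native residue
#' contacts exist under the 5-Angstrom heavy-atom rule, without inter-chain
#' clashes. Deterministic per seed.
#'
#' @param receptor_len,peptide_len residue counts
#'   (`receptor_len > peptide_len >= 3`).
#' @param geometry `"helix_helix"` (both chains helical) or `"strand_pair"`
#'   (both extended).
#' @param min_contacts minimum native residue contacts (>= 1).
#' @param seed integer RNG seed.
#' @param release_date optional `Date` stored on the complex.
#' @param id complex id; default derived from the seed.
#' @return a [complex_structure()].
#' @export
make_toy_complex <- function(receptor_len = 40, peptide_len = 10,
                             geometry = c("helix_helix", "strand_pair"),
                             min_contacts = 4, seed = 1,
                             release_date = as.Date(NA), id = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(receptor_len > peptide_len, peptide_len >= 3, min_contacts >= 1)
  dh <- if (geometry == "helix_helix") DIHEDRALS$helix else DIHEDRALS$strand
  with_seed(seed, {
    rec_seq <- random_sequence(receptor_len)
    pep_seq <- random_sequence(peptide_len)
    rec <- canonicalize_chain(build_ideal_chain("R", "receptor", rec_seq,
                                                dh["phi"], dh["psi"]))
    pep <- canonicalize_chain(build_ideal_chain("P", "peptide", pep_seq,
                                                dh["phi"], dh["psi"]))
    pep <- transform_chain(pep, translation = c(stats::runif(1, -1, 1), 0, 0))
    rec_xyz <- select_atoms(rec, "heavy")$xyz

    # bounded deterministic search: approach distance x spin about the
    # peptide axis x axial shift, tightest-first
    cx <- NULL
    cid <- id %||% sprintf("SYN%05d_RP", abs(seed) %% 100000)
    for (target in seq(3.2, 2.4, by = -0.2)) {
      for (spin in c(0, 90, 180, 270)) {
        for (shift in c(0, -3, 3)) {
          pep_c <- transform_chain(pep, rotation = rotation_about_axis(c(1, 0, 0), spin),
                                   translation = c(shift, 0, 0))
          offset <- dock_offset(rec_xyz, select_atoms(pep_c, "heavy")$xyz, target)
          pep_t <- transform_chain(pep_c, translation = c(0, 0, offset))
          cand <- complex_structure(cid, rec, pep_t, release_date)
          if (nrow(native_contacts(cand, 5.0)$pairs) >= min_contacts) cx <- cand
          if (!is.null(cx)) break
        }
        if (!is.null(cx)) break
      }
      if (!is.null(cx)) break
    }
    if (is.null(cx)) stop("peptide placement failed after bounded retries")
    cx
  })
}

# Smallest z-offset (searched downward by bisection) giving a minimum
# inter-chain heavy-atom distance of `target` Angstrom.
dock_offset <- function(rec_xyz, pep_xyz, target) {
  f <- function(t) min_interchain_dist(rec_xyz,
                                       sweep(pep_xyz, 2, c(0, 0, t), "+")) - target
  lo <- 0; hi <- 80
  if (f(lo) > 0) return(lo)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  hi
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Apply a controlled error to a prediction
#'
#' The receptor is untouched; the peptide is (in order) relocated to a
#' different surface patch when `wrong_site` (seeded patch, centroid
#' displacement at least 20 Angstrom), rotated by `rotation` degrees about a
#' seeded random axis through its centroid, translated by `translation`
#' Angstrom along a seeded random direction, and perturbed with per-atom
#' Gaussian noise of standard deviation `internal_noise_sigma`.
#'
#' @param native a `ComplexStructure`.
#' @param translation rigid translation magnitude, Angstrom.
#' @param rotation rigid rotation, degrees.
#' @param internal_noise_sigma per-coordinate Gaussian sigma, Angstrom.
#' @param wrong_site relocate the peptide to a different binding site.
#' @param seed integer RNG seed.
#' @return a `ComplexStructure` playing the role of a predicted model.
#' @export
perturb_prediction <- function(native, translation = 0, rotation = 0,
                               internal_noise_sigma = 0, wrong_site = FALSE,
                               seed = 1) {
  stopifnot(translation >= 0, rotation >= 0, internal_noise_sigma >= 0)
  with_seed(seed, {
    pep <- native$peptide
    if (wrong_site) pep <- relocate_wrong_site(native$receptor, pep)
    if (rotation > 0) {
      xyz <- as.matrix(pep$atoms[, c("x", "y", "z")])
      cen <- colMeans(xyz)
      R <- rotation_about_axis(random_unit_vector(), rotation)
      pep <- transform_chain(pep, rotation = R,
                             translation = as.numeric(cen - cen %*% R))
    }
    if (translation > 0)
      pep <- transform_chain(pep, translation = translation * random_unit_vector())
    if (internal_noise_sigma > 0) {
      n <- nrow(pep$atoms)
      pep$atoms$x <- pep$atoms$x + stats::rnorm(n, 0, internal_noise_sigma)
      pep$atoms$y <- pep$atoms$y + stats::rnorm(n, 0, internal_noise_sigma)
      pep$atoms$z <- pep$atoms$z + stats::rnorm(n, 0, internal_noise_sigma)
    }
    out <- native
    out$peptide <- pep
    out
  })
}

# Move the peptide to the opposite receptor face near the far end of the
# receptor axis, then re-dock radially to ~4 A minimum distance. Consumes
# RNG (axial end jitter) from the caller's seeded stream.
relocate_wrong_site <- function(receptor, pep) {
  ca <- select_atoms(receptor, "CA")$xyz
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  ax <- sv$v[, 1]                              # receptor principal axis
  rec_xyz <- select_atoms(receptor, "heavy")$xyz
  pep_xyz <- as.matrix(pep$atoms[, c("x", "y", "z")])
  pc <- colMeans(pep_xyz)
  rel <- pc - cen
  a1 <- sum(rel * ax)
  radial <- rel - a1 * ax
  rn <- sqrt(sum(radial^2))
  u <- if (rn > 1e-6) -radial / rn else {      # opposite face
    v <- random_unit_vector(); v <- v - sum(v * ax) * ax; v / sqrt(sum(v^2))
  }
  span <- range(sweep(ca, 2, cen) %*% ax)
  far <- if (a1 <= mean(span)) span[2] - 3 else span[1] + 3
  far <- far + stats::runif(1, -1, 1)
  f <- function(s) {
    tgt <- cen + far * ax + s * u
    min_interchain_dist(rec_xyz, sweep(pep_xyz, 2, tgt - pc, "+")) - 3.2
  }
  lo <- 0; hi <- 60
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  tgt <- cen + far * ax + hi * u
  if (sqrt(sum((tgt - pc)^2)) < 20) {          # push further out along the axis
    far <- far + sign(far - a1) * 10
    tgt <- cen + far * ax + hi * u
  }
  transform_chain(pep, translation = as.numeric(tgt - pc))
}

# ---- synthetic MSAs -------------------------------------------------------

COEVOLVE_SYMBOLS <- c("A", "L", "E", "K")   # 4-symbol alphabet for planted pairs

# Analytic MI (bits) of the mixture joint used for planted coevolving pairs:
# weight w on a perfectly-correlated component, 1-w on independence, both
# with uniform marginals over k symbols.
mixture_mi <- function(w, k) {
  p1 <- w / k + (1 - w) / k^2
  p2 <- (1 - w) / k^2
  t1 <- k * p1 * log2(p1 * k^2)
  t2 <- if (w < 1) (k^2 - k) * p2 * log2(p2 * k^2) else 0
  t1 + t2
}

# Mixing weight hitting a target MI, by bisection to 1e-6 bits.
solve_mixture_weight <- function(target_bits, k = length(COEVOLVE_SYMBOLS)) {
  if (target_bits < 0 || target_bits > log2(k) + 1e-12)
    stop("infeasible MI target: must lie in [0, ", round(log2(k), 4), "] bits")
  lo <- 0; hi <- 1
  for (i in 1:80) {                 # interval 2^-80: MI well within 1e-6 bits
    mid <- (lo + hi) / 2
    if (mixture_mi(mid, k) < target_bits) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

sample_background_column <- function(depth) {
  syms <- sample(AA1, 6)
  pr <- stats::rexp(6); pr <- pr / sum(pr)
  sample(syms, depth, replace = TRUE, prob = pr)
}

sample_conserved_column <- function(depth) {
  major <- sample(AA1, 1)
  others <- sample(setdiff(AA1, major), 5)
  sample(c(major, others), depth, replace = TRUE,
         prob = c(0.9, rep(0.02, 5)))
}

#' Generate coupled receptor and peptide MSAs with planted structure
#'
#' Per-column categorical sampling: a `conserved_fraction` of columns
#' concentrate 90% of their mass on one symbol; planted coevolving column
#' pairs are sampled from a two-column joint distribution (a mixture of a
#' perfectly-correlated and an independent component over a 4-symbol
#' alphabet) whose analytic mutual information equals the requested target,
#' with the mixing weight solved by bisection to 1e-6 bits. Row i of the
#' receptor MSA and row i of the peptide MSA belong to the same (by default
#' unique) species, so [pair_by_species()] reconstitutes the generating
#' pairs exactly. Deterministic per seed.
#'
#' @param depth number of rows (>= 2), query included.
#' @param receptor_len,peptide_len column counts.
#' @param conserved_fraction share of columns that are strongly conserved.
#' @param coevolving_pairs list of `c(receptor_col, peptide_col, target_bits)`
#'   triples (targets at most 2 bits, the 4-symbol alphabet entropy).
#' @param species_pool number of distinct species tags; the default (one per
#'   non-query row) makes species unique so pairing is exact.
#' @param seed integer RNG seed.
#' @return list with `receptor` and `peptide` `Msa` objects; the attribute
#'   `mixture_weights` records the solved weight per planted pair.
#' @export
make_synthetic_msas <- function(depth, receptor_len, peptide_len,
                                conserved_fraction = 0.3,
                                coevolving_pairs = list(),
                                species_pool = NULL, seed = 1) {
  stopifnot(depth >= 2)
  k <- length(COEVOLVE_SYMBOLS)
  weights <- vapply(coevolving_pairs, function(p) solve_mixture_weight(p[3], k),
                    numeric(1))
  with_seed(seed, {
    rec_cols <- matrix("", depth, receptor_len)
    pep_cols <- matrix("", depth, peptide_len)
    co_r <- vapply(coevolving_pairs, `[`, numeric(1), 1)
    co_p <- vapply(coevolving_pairs, `[`, numeric(1), 2)
    free_r <- setdiff(seq_len(receptor_len), co_r)
    free_p <- setdiff(seq_len(peptide_len), co_p)
    cons_r <- sample(free_r, round(conserved_fraction * length(free_r)))
    cons_p <- sample(free_p, round(conserved_fraction * length(free_p)))
    for (j in free_r) rec_cols[, j] <- if (j %in% cons_r)
      sample_conserved_column(depth) else sample_background_column(depth)
    for (j in free_p) pep_cols[, j] <- if (j %in% cons_p)
      sample_conserved_column(depth) else sample_background_column(depth)
    for (i in seq_along(coevolving_pairs)) {
      w <- weights[i]
      correlated <- stats::runif(depth) < w
      a <- sample.int(k, depth, replace = TRUE)
      b <- ifelse(correlated, a, sample.int(k, depth, replace = TRUE))
      rec_cols[, co_r[i]] <- COEVOLVE_SYMBOLS[a]
      pep_cols[, co_p[i]] <- COEVOLVE_SYMBOLS[b]
    }
    # query row: modal symbol per column (no gaps by construction)
    mode_of <- function(v) names(which.max(table(v)))
    rec_cols[1, ] <- apply(rec_cols, 2, mode_of)
    pep_cols[1, ] <- apply(pep_cols, 2, mode_of)

    n_sp <- species_pool %||% (depth - 1)
    sp <- c(NA_character_,
            sprintf("SP%06d", rep_len(seq_len(n_sp), depth - 1)))
    rec_ids <- c("receptor_query",
                 sprintf("rec%06d_%s", 2:depth, sp[-1]))
    pep_ids <- c("peptide_query",
                 sprintf("pep%06d_%s", 2:depth, sp[-1]))
    out <- list(
      receptor = msa(rec_ids, apply(rec_cols, 1, paste, collapse = ""),
                     species = sp),
      peptide = msa(pep_ids, apply(pep_cols, 1, paste, collapse = ""),
                    species = sp)
    )
    attr(out, "mixture_weights") <- weights
    out
  })
}

# ---- match libraries ------------------------------------------------------

# Relabel a fraction of residues with different amino acids (labels only;
# coordinates untouched, so structural similarity is preserved).
mutate_chain_sequence <- function(chain, fraction) {
  n <- chain$nres
  pick <- sample(n, max(1, round(fraction * n)))
  for (ri in pick) {
    new1 <- sample(setdiff(AA1, chain$seq[ri]), 1)
    chain$seq[ri] <- new1
    chain$atoms$resname[chain$atoms$seq_index == ri] <- AA_123[new1]
  }
  chain
}

jitter_chain <- function(chain, sigma) {
  n <- nrow(chain$atoms)
  chain$atoms$x <- chain$atoms$x + stats::rnorm(n, 0, sigma)
  chain$atoms$y <- chain$atoms$y + stats::rnorm(n, 0, sigma)
  chain$atoms$z <- chain$atoms$z + stats::rnorm(n, 0, sigma)
  chain
}

#' Build a dated match library with planted homologs
#'
#' Plants three entry classes around a query complex: true binding-site
#' matches (receptor homologs, ~80% sequence identity and near-identical
#' fold, partner bound at the query site), homologous non-matches (same
#' receptors with the partner relocated to a different site, >10 Angstrom
#' partner RMSD), and non-homologous decoys (extended-geometry receptors
#' with random sequences). Matches and non-matches are dated inside
#' `date_window` (strictly before `cutoff_date`); `n_post_cutoff` extra
#' entries are match-like but dated after the cutoff, so the date filter
#' must exclude them.
#'
#' @param query a `ComplexStructure`.
#' @param n_match,n_homolog_nonmatch,n_nonhomolog,n_post_cutoff entry counts.
#' @param date_window `c(earliest, latest)` dates for pre-cutoff entries.
#' @param cutoff_date the training cutoff the search will be run with.
#' @param seed integer RNG seed.
#' @return list with `entries` (list of [match_library_entry()]) and
#'   `expected_matches` (= `n_match`).
#' @export
make_match_library <- function(query, n_match = 2, n_homolog_nonmatch = 3,
                               n_nonhomolog = 4, n_post_cutoff = 1,
                               date_window = as.Date(c("2018-01-01", "2021-01-01")),
                               cutoff_date = as.Date("2021-06-01"), seed = 1) {
  date_window <- as.Date(date_window)
  cutoff_date <- as.Date(cutoff_date)
  stopifnot(date_window[2] < cutoff_date)
  with_seed(seed, {
    pre_date <- function() date_window[1] +
      sample.int(as.integer(date_window[2] - date_window[1]), 1) - 1
    post_date <- function() cutoff_date + sample.int(300, 1)

    homolog_copy <- function() {
      rec <- jitter_chain(mutate_chain_sequence(query$receptor, 0.2), 0.05)
      pep <- jitter_chain(query$peptide, 0.05)
      list(rec = rec, pep = pep)
    }
    entries <- list()
    add <- function(entry) entries[[length(entries) + 1]] <<- entry

    for (i in seq_len(n_match)) {
      h <- homolog_copy()
      cx <- complex_structure(sprintf("MAT%02d_RP", i), h$rec, h$pep)
      add(match_library_entry(cx, pre_date(), cx$id))
    }
    for (i in seq_len(n_homolog_nonmatch)) {
      h <- homolog_copy()
      moved <- relocate_wrong_site(h$rec, h$pep)
      cx <- complex_structure(sprintf("NON%02d_RP", i), h$rec, moved)
      add(match_library_entry(cx, pre_date(), cx$id))
    }
    for (i in seq_len(n_nonhomolog)) {
      cx <- make_toy_complex(query$receptor$nres + 5, query$peptide$nres,
                             geometry = "strand_pair",
                             seed = sample.int(1e6, 1),
                             id = sprintf("DEC%02d_RP", i))
      add(match_library_entry(cx, pre_date(), cx$id))
    }
    for (i in seq_len(n_post_cutoff)) {
      h <- homolog_copy()
      cx <- complex_structure(sprintf("PST%02d_RP", i), h$rec, h$pep)
      add(match_library_entry(cx, post_date(), cx$id))
    }
    list(entries = entries, expected_matches = n_match)
  })
}

#' Write a match library to disk with its manifest
#'
#' @param library output of [make_match_library()] (or a bare entry list).
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_match_library <- function(library, dir) {
  entries <- if (!is.null(library$entries)) library$entries else library
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(entries, function(e) {
    p <- file.path(dir, paste0(e$entry_id, ".pdb"))
    cx <- e$complex
    cx$release_date <- e$release_date
    write_structure(cx, p)
    data.frame(entry_id = e$entry_id, path = p,
               receptor_chain = cx$receptor$id, partner_chain = cx$peptide$id,
               release_date = format(e$release_date), stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "library.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
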