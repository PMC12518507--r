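# MSA I/O, context-column trimming, species pairing with the shuffling null,
# mutual information, Jensen-Shannon conservation, hydrophobicity, and
# peptide-sequence ablation variants.

#' @importFrom Biostrings readBStringSet readAAMultipleAlignment BStringSet
#'   writeXStringSet pairwiseAlignment pid
NULL

#' Construct an MSA object
#'
#' Row 1 is the query and must carry no gaps; all rows share one width.
#'
#' @param ids sequence identifiers (headers).
#' @param aligned aligned sequences (characters over amino acids + `-`).
#' @param species optional species tags; when `NULL` they are extracted from
#'   `ids` via [extract_species()].
#' @param species_regex optional regex with one capture group overriding the
#'   default species extraction.
#' @return object of class `Msa` with fields `query`, `ids`, `species`,
#'   `aligned`, `n_cols`.
#' @export
msa <- function(ids, aligned, species = NULL, species_regex = NULL) {
  stopifnot(length(ids) == length(aligned), length(aligned) >= 1)
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: row widths ", paste(unique(widths), collapse = ", "))
  if (grepl("-", aligned[1], fixed = TRUE))
    stop("query row (row 1) must not contain gaps")
  if (is.null(species)) species <- extract_species(ids, species_regex)
  structure(list(query = aligned[1], ids = as.character(ids),
                 species = as.character(species), aligned = as.character(aligned),
                 n_cols = widths[1]),
            class = "Msa")
}

msa_depth <- function(x) length(x$aligned)

#' Does an MSA meet a minimum depth?
#'
#' Depth filter used to decide whether a peptide MSA is deep enough to be
#' informative; the default bound is 50 sequences.
#'
#' @param x an `Msa`.
#' @param min_depth minimum number of rows (query included).
#' @return logical.
#' @export
msa_depth_ok <- function(x, min_depth = 50) msa_depth(x) >= min_depth

#' Extract species tags from sequence headers
#'
#' Default conventions tried in order: a UniProt-style `OX=<taxid>` field,
#' then an `_SPECIES` suffix on the first whitespace-delimited token.
#' Headers matching neither yield `NA` (unknown species).
#'
#' @param ids header strings.
#' @param regex optional single-capture-group regex overriding the defaults.
#' @return character vector of tags (`NA` = unknown).
#' @export
extract_species <- function(ids, regex = NULL) {
  out <- rep(NA_character_, length(ids))
  pats <- if (is.null(regex)) c("OX=([^[:space:]]+)", "^[^[:space:]]*_([A-Za-z0-9]+)$")
          else regex
  for (p in pats) {
    tok <- if (startsWith(p, "^")) sub("[[:space:]].*$", "", ids) else ids
    m <- regmatches(tok, regexec(p, tok))
    hit <- vapply(m, length, integer(1)) == 2 & is.na(out)
    out[hit] <- vapply(m[hit], `[`, character(1), 2)
  }
  out
}

#' Read an MSA from A3M, aligned FASTA or Stockholm
#'
#' The first sequence is taken as the query. For A3M, lowercase insertion
#' states are removed so that the remaining columns index query positions.
#'
#' @param path file path.
#' @param format `"a3m"`, `"fasta"` or `"stockholm"`.
#' @param species_regex passed to [msa()].
#' @return an `Msa`.
#' @export
read_msa <- function(path, format = c("a3m", "fasta", "stockholm"),
                     species_regex = NULL) {
  format <- match.arg(format)
  if (format == "stockholm") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(aln)
    ids <- names(seqs)
  } else {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0) stop("empty MSA file: ", path)
    seqs <- as.character(ss)
    ids <- names(ss)
    if (format == "a3m") seqs <- gsub("[a-z.]", "", seqs)
  }
  seqs <- toupper(seqs)
  msa(ids, unname(seqs), species_regex = species_regex)
}

#' Write an MSA as aligned FASTA
#'
#' @param x an `Msa` or `PairedMsa`.
#' @param path output file path.
#' @return `path`, invisibly. For a `PairedMsa` the first line of the file is
#'   a `#` comment recording the block ranges and paired-row count.
#' @export
write_msa <- function(x, path) {
  if (inherits(x, "PairedMsa")) {
    hdr <- sprintf("# receptor_cols=1-%d peptide_cols=%d-%d paired_rows=%d",
                   x$chain_split, x$chain_split + 1, x$n_cols, x$paired_rows)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste0(">", x$ids, "\n", x$aligned), con)
    return(invisible(path))
  }
  ss <- Biostrings::BStringSet(stats::setNames(x$aligned, x$ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Trim a context-extended MSA to the peptide columns
#'
#' After building an MSA for a peptide with flanking context residues, all
#' columns are removed except those corresponding to the delimited peptide.
#' Because the query row carries no gaps, column j indexes query position j.
#'
#' @param full_msa an `Msa` over the context-extended query.
#' @param peptide_span inclusive 1-based `c(start, end)` positions of the
#'   peptide in the full-length query.
#' @return an `Msa` over the retained columns (row order and species
#'   preserved).
#' @export
map_context_columns <- function(full_msa, peptide_span) {
  stopifnot(length(peptide_span) == 2)
  s <- as.integer(peptide_span[1]); e <- as.integer(peptide_span[2])
  if (s < 1 || e > full_msa$n_cols || s > e)
    stop("peptide span [", s, ", ", e, "] outside query (1..",
         full_msa$n_cols, ")")
  msa(full_msa$ids, substr(full_msa$aligned, s, e), species = full_msa$species)
}

row_identity_to_query <- function(aligned, query) {
  qc <- strsplit(query, "")[[1]]
  vapply(strsplit(aligned, ""), function(rc)
    mean(rc == qc & rc != "-"), numeric(1))
}

#' Pair receptor and peptide MSAs by species
#'
#' Rows sharing a species tag are paired rank-to-rank after ranking within
#' each species by percent identity to the respective query (the
#' AF2-Multimer convention). The two query rows are always paired. Leftover
#' and unknown-species rows are placed block-diagonally, gap-filled in the
#' other chain's block.
#'
#' @param receptor_msa,peptide_msa `Msa` objects (row 1 = query).
#' @return object of class `PairedMsa` with `aligned` (concatenated rows),
#'   `ids`, `species`, `block` (`"paired"`, `"receptor_only"` or
#'   `"peptide_only"` per row), `chain_split` (= receptor width), `n_cols`,
#'   `paired_rows` (count of paired rows, query included),
#'   `unpaired_receptor_rows`, `unpaired_peptide_rows`.
#' @export
pair_by_species <- function(receptor_msa, peptide_msa) {
  Lr <- receptor_msa$n_cols; Lp <- peptide_msa$n_cols
  gap_r <- strrep("-", Lr); gap_p <- strrep("-", Lp)

  # ranked (by identity desc, stable) non-query row indices per species
  ranked <- function(m) {
    idx <- seq_along(m$aligned)[-1]
    if (!length(idx)) return(list())
    pid <- row_identity_to_query(m$aligned[idx], m$query)
    ord <- idx[order(-pid, idx)]
    sp <- m$species[ord]
    split(ord, factor(sp, levels = unique(sp[!is.na(sp)])))
  }
  rr <- ranked(receptor_msa); pr <- ranked(peptide_msa)
  shared <- intersect(names(rr), names(pr))

  ids <- paste0(receptor_msa$ids[1], "|", peptide_msa$ids[1])
  aligned <- paste0(receptor_msa$aligned[1], peptide_msa$aligned[1])
  species <- NA_character_
  block <- "paired"
  used_r <- used_p <- integer(0)
  for (sp in shared) {
    k <- min(length(rr[[sp]]), length(pr[[sp]]))
    for (i in seq_len(k)) {
      ri <- rr[[sp]][i]; pi <- pr[[sp]][i]
      ids <- c(ids, paste0(receptor_msa$ids[ri], "|", peptide_msa$ids[pi]))
      aligned <- c(aligned, paste0(receptor_msa$aligned[ri], peptide_msa$aligned[pi]))
      species <- c(species, sp)
      block <- c(block, "paired")
      used_r <- c(used_r, ri); used_p <- c(used_p, pi)
    }
  }
  n_paired <- length(aligned)
  rest_r <- setdiff(seq_along(receptor_msa$aligned)[-1], used_r)
  for (ri in rest_r) {
    ids <- c(ids, receptor_msa$ids[ri])
    aligned <- c(aligned, paste0(receptor_msa$aligned[ri], gap_p))
    species <- c(species, receptor_msa$species[ri])
    block <- c(block, "receptor_only")
  }
  rest_p <- setdiff(seq_along(peptide_msa$aligned)[-1], used_p)
  for (pi in rest_p) {
    ids <- c(ids, peptide_msa$ids[pi])
    aligned <- c(aligned, paste0(gap_r, peptide_msa$aligned[pi]))
    species <- c(species, peptide_msa$species[pi])
    block <- c(block, "peptide_only")
  }
  structure(list(aligned = aligned, ids = ids, species = species,
                 block = block, chain_split = Lr, n_cols = Lr + Lp,
                 paired_rows = n_paired,
                 unpaired_receptor_rows = length(rest_r),
                 unpaired_peptide_rows = length(rest_p)),
            class = "PairedMsa")
}

#' Randomize receptor-peptide pairings (shuffling null)
#'
#' Permutes the peptide-block halves of the paired rows uniformly at random
#' (seeded). The query row is exempt and the unpaired blocks are untouched,
#' so every block retains exactly the same multiset of sequences.
#'
#' @param paired a `PairedMsa`.
#' @param seed integer RNG seed.
#' @return a `PairedMsa` with shuffled pairings.
#' @export
shuffle_pairings <- function(paired, seed) {
  stopifnot(inherits(paired, "PairedMsa"), paired$paired_rows >= 1)
  idx <- seq_len(paired$paired_rows)[-1]        # non-query paired rows
  if (length(idx) < 2) return(paired)
  perm <- with_seed(seed, sample(idx))
  k <- paired$chain_split
  rec_half <- substr(paired$aligned[idx], 1, k)
  pep_half <- substr(paired$aligned[perm], k + 1, paired$n_cols)
  paired$aligned[idx] <- paste0(rec_half, pep_half)
  paired$ids[idx] <- paste0(sub("\\|.*$", "", paired$ids[idx]), "|",
                            sub("^.*\\|", "", paired$ids[perm]))
  paired$species[idx] <- NA_character_
  paired
}

msa_char_matrix <- function(x) {
  do.call(rbind, strsplit(x$aligned, ""))
}

#' Mutual information between two alignment columns
#'
#' Plug-in estimate in bits over the rows with no gap in either column
#' (pairwise-complete policy; set `gaps_as_symbol = TRUE` to keep gaps as a
#' 21st symbol). No pseudocount is applied.
#'
#' @param x an `Msa` or `PairedMsa`.
#' @param col_a,col_b 1-based column indices (for a `PairedMsa`, in the
#'   concatenated receptor+peptide coordinate system).
#' @param gaps_as_symbol treat `-` as an ordinary symbol.
#' @return MI in bits (non-negative).
#' @export
column_mi <- function(x, col_a, col_b, gaps_as_symbol = FALSE) {
  a <- substr(x$aligned, col_a, col_a)
  b <- substr(x$aligned, col_b, col_b)
  if (!gaps_as_symbol) {
    keep <- a != "-" & b != "-"
    a <- a[keep]; b <- b[keep]
  }
  n <- length(a)
  if (n < 2) stop("fewer than 2 usable rows after gap policy")
  joint <- table(a, b) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  ex <- outer(pa, pb)
  nz <- joint > 0
  max(0, sum(joint[nz] * log2(joint[nz] / ex[nz])))
}

#' Inter-chain mutual information summary for a paired MSA
#'
#' MI is computed for every (receptor column, peptide column) pair over the
#' paired rows only (unpaired rows are gap-filled and drop out under the
#' pairwise-complete gap policy).
#'
#' @param paired a `PairedMsa` with at least 2 paired rows.
#' @return list of class `MiResult` with `per_pair` (data.frame
#'   `receptor_col`, `peptide_col`, `mi_bits`), `mean_interchain`,
#'   `max_interchain`.
#' @export
interchain_mi_summary <- function(paired) {
  stopifnot(inherits(paired, "PairedMsa"))
  if (paired$paired_rows < 2) stop("need at least 2 paired rows")
  k <- paired$chain_split
  sub <- paired
  sub$aligned <- paired$aligned[seq_len(paired$paired_rows)]
  grid <- expand.grid(receptor_col = seq_len(k),
                      peptide_col = (k + 1):paired$n_cols)
  grid$mi_bits <- mapply(function(r, p) column_mi(sub, r, p),
                         grid$receptor_col, grid$peptide_col)
  structure(list(per_pair = grid,
                 mean_interchain = mean(grid$mi_bits),
                 max_interchain = max(grid$mi_bits)),
            class = "MiResult")
}

#' Jensen-Shannon divergence conservation profile
#'
#' Per column, `JSD(p, q) = 0.5*KL(p||m) + 0.5*KL(q||m)` with `m = (p+q)/2`
#' and base-2 logarithms (bounded in \[0, 1\]), where `p` is the column
#' amino-acid frequency over non-gap rows and `q` a background. The score is
#' multiplied by `(1 - gap_fraction)` as a gap penalty. All-gap columns
#' score 0 and are flagged.
#'
#' @param x an `Msa` with at least 2 rows.
#' @param background `"uniform"`, `"blosum62"`, or a named 20-vector of
#'   frequencies.
#' @return list of class `ConservationProfile`: `jsd`, `gap_fraction`,
#'   `all_gap` (logical flags), each of length `n_cols`.
#' @export
jsd_conservation <- function(x, background = c("uniform", "blosum62")) {
  if (msa_depth(x) < 2) stop("need at least 2 rows")
  q <- if (is.numeric(background)) {
    stopifnot(length(background) == 20)
    background[AA1] / sum(background)
  } else {
    switch(match.arg(background),
           uniform = stats::setNames(rep(1 / 20, 20), AA1),
           blosum62 = BLOSUM62_BACKGROUND[AA1])
  }
  cm <- msa_char_matrix(x)
  n_cols <- ncol(cm)
  jsd <- gapf <- numeric(n_cols)
  all_gap <- logical(n_cols)
  for (j in seq_len(n_cols)) {
    col <- cm[, j]
    gapf[j] <- mean(col == "-")
    aa <- col[col %in% AA1]
    if (!length(aa)) { all_gap[j] <- gapf[j] == 1; jsd[j] <- 0; next }
    p <- table(factor(aa, levels = AA1)) / length(aa)
    m <- (p + q) / 2
    kl <- function(u, v) { nz <- u > 0; sum(u[nz] * log2(u[nz] / v[nz])) }
    jsd[j] <- (0.5 * kl(p, m) + 0.5 * kl(q, m)) * (1 - gapf[j])
  }
  structure(list(jsd = jsd, gap_fraction = gapf, all_gap = all_gap),
            class = "ConservationProfile")
}

#' Peptide sequence ablation variants
#'
#' `mask` replaces every residue with the unknown token `X`; `polyG` with
#' glycine; `scramble` applies a seeded permutation preserving composition,
#' guaranteed to differ from the input whenever any distinct permutation
#' exists.
#'
#' @param seq amino-acid string (non-empty).
#' @param mode `"mask"`, `"scramble"` or `"polyG"`.
#' @param seed RNG seed for `scramble`.
#' @return the modified sequence.
#' @export
peptide_sequence_variants <- function(seq, mode = c("mask", "scramble", "polyG"),
                                      seed = 1) {
  mode <- match.arg(mode)
  stopifnot(nchar(seq) >= 1)
  n <- nchar(seq)
  if (mode == "mask") return(strrep("X", n))
  if (mode == "polyG") return(strrep("G", n))
  ch <- strsplit(seq, "")[[1]]
  if (length(unique(ch)) == 1) return(seq)      # no distinct permutation
  with_seed(seed, {
    repeat {
      out <- paste(sample(ch), collapse = "")
      if (out != seq) break
    }
    out
  })
}

#' Mean hydrophobicity of a residue set
#'
#' Arithmetic mean of per-residue scale values (Kyte-Doolittle by default).
#' Residues absent from the scale (e.g. `X`) are skipped; the number skipped
#' is attached as attribute `n_skipped`.
#'
#' @param residues 1-letter codes (string or character vector).
#' @param scale named numeric per-residue table.
#' @return mean scale value with attribute `n_skipped`.
#' @export
mean_hydrophobicity <- function(residues, scale = KYTE_DOOLITTLE) {
  if (length(residues) == 1 && nchar(residues[1]) > 1)
    residues <- strsplit(residues, "")[[1]]
  vals <- scale[residues]
  n_skip <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no residues with a scale value")
  structure(mean(vals), n_skipped = n_skip)
}

#' Kyte-Doolittle hydropathy scale
#' @export
kyte_doolittle_scale <- function() KYTE_DOOLITTLE

#' @export
print.Msa <- function(x, ...) {
  cat(sprintf("Msa: %d rows x %d columns (%d with species tags)\n",
              msa_depth(x), x$n_cols, sum(!is.na(x$species))))
  invisible(x)
}

#' @export
print.PairedMsa <- function(x, ...) {
  cat(sprintf(
    "PairedMsa: %d+%d columns; %d paired rows (incl. query), %d receptor-only, %d peptide-only\n",
    x$chain_split, x$n_cols - x$chain_split, x$paired_rows,
    x$unpaired_receptor_rows, x$unpaired_peptide_rows))
  invisible(x)
}
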