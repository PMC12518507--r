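# MSA I/O, context trimming, species pairing, the shuffling null, MI, JSD,
# ablation variants and hydrophobicity.

mini_msa <- function(rows, ids = NULL, species = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(rows))
  msa(ids, rows, species = species)
}

test_that("FASTA and A3M reading: widths, insertion removal, round-trip", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACDEF", ">a OX=9606", "AC-EF", ">b OX=10090", "AADE-"), fa)
  m <- read_msa(fa, "fasta")
  expect_equal(m$n_cols, 5)
  expect_equal(length(m$aligned), 3)
  expect_equal(m$species, c(NA, "9606", "10090"))

  a3m <- tempfile(fileext = ".a3m")
  writeLines(c(">q", "ACDEF", ">a", "ACxyDEF"), a3m)   # 2 lowercase insertions
  m2 <- read_msa(a3m, "a3m")
  expect_equal(m2$n_cols, 5)
  expect_identical(m2$aligned[2], "ACDEF")

  out <- tempfile(fileext = ".fasta")
  write_msa(m, out)
  back <- read_msa(out, "fasta")
  expect_identical(back$aligned, m$aligned)
  expect_identical(back$ids, m$ids)
})

test_that("Stockholm fixtures round-trip to the same row set", {
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "",
               "q        ACDEF",
               "a_HUMAN  AC-EF",
               "b_MOUSE  AADE-",
               "//"), sto)
  m <- read_msa(sto, "stockholm")
  expect_equal(m$n_cols, 5)
  expect_setequal(m$aligned, c("ACDEF", "AC-EF", "AADE-"))
  expect_equal(m$species[2:3], c("HUMAN", "MOUSE"))
  expect_error(read_msa(tempfile(fileext = ".fasta"), "fasta"))
})

test_that("context-column trimming keeps exactly the peptide span", {
  rows <- c(strrep("A", 30), paste0(strrep("-", 5), strrep("C", 20),
                                    strrep("-", 5)))
  m <- mini_msa(rows)
  expect_identical(map_context_columns(m, c(1, 30))$aligned, m$aligned)
  sub <- map_context_columns(m, c(10, 20))
  expect_equal(sub$n_cols, 11)
  expect_identical(sub$aligned[1], strrep("A", 11))
  expect_error(map_context_columns(m, c(0, 10)), "outside")
  expect_error(map_context_columns(m, c(5, 31)), "outside")

  # after A3M insertion removal, columns still index query positions
  a3m <- tempfile(fileext = ".a3m")
  writeLines(c(">q", "ACDEFGH", ">a", "ACDxxEFGH"), a3m)
  m2 <- read_msa(a3m, "a3m")
  sub2 <- map_context_columns(m2, c(4, 6))
  expect_identical(sub2$aligned[1], "EFG")
  expect_identical(sub2$aligned[2], "EFG")
})

test_that("species pairing: shared species, no overlap, identity-rank rule", {
  rec <- mini_msa(c("AAAA", "AAAC", "AAAD"), species = c(NA, "A", "B"))
  pep <- mini_msa(c("WWW", "WWC", "WWD"), species = c(NA, "B", "C"))
  pm <- pair_by_species(rec, pep)
  expect_equal(pm$paired_rows, 2)                  # query + species B
  expect_equal(pm$unpaired_receptor_rows, 1)
  expect_equal(pm$unpaired_peptide_rows, 1)
  expect_true(all(substr(pm$aligned[pm$block == "receptor_only"], 5, 7) == "---"))
  expect_true(all(substr(pm$aligned[pm$block == "peptide_only"], 1, 4) == "----"))

  none <- pair_by_species(mini_msa(c("AAAA", "AAAC"), species = c(NA, "X")),
                          mini_msa(c("WWW", "WWC"), species = c(NA, "Y")))
  expect_equal(none$paired_rows, 1)                # only the query row

  # two receptor rows, one peptide row, same species: best identity pairs
  rec2 <- mini_msa(c("AAAA", "ACCC", "AAAC"), species = c(NA, "S", "S"))
  pep2 <- mini_msa(c("WWW", "WWC"), species = c(NA, "S"))
  pm2 <- pair_by_species(rec2, pep2)
  expect_equal(pm2$paired_rows, 2)
  # row 3 ("AAAC", identity 3/4) outranks row 2 ("ACCC", identity 1/4)
  expect_identical(substr(pm2$aligned[2], 1, 4), "AAAC")
  expect_equal(pm2$unpaired_receptor_rows, 1)
})

test_that("shuffling preserves per-block sequence multisets and the query", {
  sm <- make_synthetic_msas(depth = 40, receptor_len = 8, peptide_len = 6,
                            seed = 3)
  pm <- pair_by_species(sm$receptor, sm$peptide)
  sh <- shuffle_pairings(pm, seed = 11)
  k <- pm$chain_split
  expect_identical(sh$aligned[1], pm$aligned[1])
  expect_identical(sort(substr(sh$aligned, 1, k)),
                   sort(substr(pm$aligned, 1, k)))
  expect_identical(sort(substr(sh$aligned, k + 1, pm$n_cols)),
                   sort(substr(pm$aligned, k + 1, pm$n_cols)))
  # single paired non-query row: output identical to input
  one <- pair_by_species(mini_msa(c("AAAA", "AAAC"), species = c(NA, "S")),
                         mini_msa(c("WWW", "WWC"), species = c(NA, "S")))
  expect_identical(shuffle_pairings(one, 5)$aligned, one$aligned)
})

test_that("column MI: perfect correlation, constant column, enumeration oracle", {
  m <- mini_msa(c("AC", "AC", "AC", "AC", "GT", "GT", "GT", "GT"))
  expect_equal(column_mi(m, 1, 2), 1.0)            # two symbols, uniform
  const <- mini_msa(c("AA", "AC", "AG", "AT"))
  expect_equal(column_mi(const, 1, 2), 0)

  # 8-row alignment with mixed frequencies vs hand enumeration
  rows <- c("AC", "AC", "AG", "CT", "CT", "CG", "GT", "G-")
  m8 <- mini_msa(rows)
  a <- substr(rows, 1, 1); b <- substr(rows, 2, 2)
  expect_equal(column_mi(m8, 1, 2), mi_enumeration_oracle(a, b),
               tolerance = 1e-12)
  # symmetry and self-MI = column entropy
  expect_equal(column_mi(m8, 1, 2), column_mi(m8, 2, 1), tolerance = 1e-12)
  aa <- a[b != "-"]
  expect_equal(column_mi(m8, 1, 1),
               -sum(table(a) / 8 * log2(table(a) / 8)), tolerance = 1e-12)
  expect_error(column_mi(mini_msa(c("AA", "A-", "-A")), 1, 2), "fewer than 2")
})

test_that("inter-chain MI summary finds a planted coevolving pair", {
  sm <- make_synthetic_msas(depth = 400, receptor_len = 6, peptide_len = 5,
                            conserved_fraction = 0,
                            coevolving_pairs = list(c(2, 3, 1.5)), seed = 8)
  pm <- pair_by_species(sm$receptor, sm$peptide)
  mi <- interchain_mi_summary(pm)
  top <- mi$per_pair[which.max(mi$per_pair$mi_bits), ]
  expect_equal(top$receptor_col, 2)
  expect_equal(top$peptide_col, 6 + 3)
  expect_gte(mi$max_interchain, mi$mean_interchain)

  cc <- pair_by_species(mini_msa(c("AA", "AA", "AA"), species = c(NA, "a", "b")),
                        mini_msa(c("CC", "CC", "CC"), species = c(NA, "a", "b")))
  mi0 <- interchain_mi_summary(cc)
  expect_equal(mi0$mean_interchain, 0)
  expect_equal(mi0$max_interchain, 0)
})

test_that("shuffled pairings lower inter-chain MI in nearly all replicates", {
  sm <- make_synthetic_msas(depth = 300, receptor_len = 5, peptide_len = 4,
                            conserved_fraction = 0,
                            coevolving_pairs = list(c(1, 1, 1.0)), seed = 2)
  pm <- pair_by_species(sm$receptor, sm$peptide)
  before <- column_mi(pm, 1, 5 + 1)
  drops <- vapply(1:40, function(s)
    column_mi(shuffle_pairings(pm, s), 1, 5 + 1) < before, logical(1))
  expect_gte(mean(drops), 0.95)
})

test_that("JSD conservation: background column scores 0, closed-form check, gaps", {
  # column distribution equal to the uniform background
  rows <- vapply(1:20, function(i) paste(pepdockeval:::AA1, collapse = ""),
                 character(1))
  m <- mini_msa(rows)   # every column uniform over the 20 residues? no: each
  # row is the full alphabet so column j is constant; build columns instead
  cols <- matrix(rep(pepdockeval:::AA1, 3), nrow = 20)
  m <- mini_msa(apply(cols, 1, paste, collapse = ""))
  prof <- jsd_conservation(m, "uniform")
  expect_equal(prof$jsd, rep(0, 3), tolerance = 1e-12)

  # fully conserved gap-free column vs uniform background: direct formula
  cons <- mini_msa(c("A", "A", "A", "A"))
  p <- c(1, rep(0, 19)); q <- rep(1 / 20, 20); mm <- (p + q) / 2
  kl <- function(u, v) sum(ifelse(u > 0, u * log2(u / v), 0))
  expect_equal(jsd_conservation(cons, "uniform")$jsd,
               0.5 * kl(p, mm) + 0.5 * kl(q, mm), tolerance = 1e-12)

  # adding gap rows strictly decreases the penalized score
  gappy <- mini_msa(c("A", "A", "A", "A", "-", "-"))
  expect_lt(jsd_conservation(gappy, "uniform")$jsd,
            jsd_conservation(cons, "uniform")$jsd)
  expect_equal(gappy_gap <- jsd_conservation(gappy)$gap_fraction, 1 / 3)

  # relabeling invariance: permute amino acids jointly in column + background
  m1 <- mini_msa(c("A", "A", "C", "D"))
  perm <- pepdockeval:::AA1[c(2:20, 1)]
  bg <- stats::setNames(rep(1 / 20, 20), pepdockeval:::AA1)
  relab <- chartr(paste(pepdockeval:::AA1, collapse = ""),
                  paste(perm, collapse = ""), c("A", "A", "C", "D"))
  expect_equal(jsd_conservation(m1, bg)$jsd,
               jsd_conservation(mini_msa(relab), bg[order(names(bg))])$jsd,
               tolerance = 1e-12)
})

test_that("peptide ablation variants: mask, polyG, composition-preserving scramble", {
  expect_identical(peptide_sequence_variants("ACDE", "mask"), "XXXX")
  expect_identical(peptide_sequence_variants("ACDE", "polyG"), "GGGG")
  sc <- peptide_sequence_variants("AACD", "scramble", seed = 7)
  expect_identical(paste(sort(strsplit(sc, "")[[1]]), collapse = ""), "AACD")
  expect_false(sc == "AACD")
  # no distinct permutation exists -> unchanged
  expect_identical(peptide_sequence_variants("AAAA", "scramble", seed = 1), "AAAA")
  # determinism
  expect_identical(peptide_sequence_variants("ACDEFGH", "scramble", seed = 4),
                   peptide_sequence_variants("ACDEFGH", "scramble", seed = 4))
})

test_that("mean hydrophobicity: exact values, mixed-case oracle, X skipped", {
  kd <- kyte_doolittle_scale()
  expect_equal(as.numeric(mean_hydrophobicity("III")), kd[["I"]])
  expect_equal(as.numeric(mean_hydrophobicity("AR")),
               (kd[["A"]] + kd[["R"]]) / 2)
  seq10 <- "ACDEFGHIKL"
  expect_equal(as.numeric(mean_hydrophobicity(seq10)),
               mean(kd[strsplit(seq10, "")[[1]]]))
  withx <- mean_hydrophobicity("AXV")
  expect_equal(attr(withx, "n_skipped"), 1)
  expect_equal(as.numeric(withx), (kd[["A"]] + kd[["V"]]) / 2)
  expect_error(mean_hydrophobicity("XX"), "no residues")
})

test_that("MSA depth filter is a sharp boundary at 50 sequences", {
  m49 <- mini_msa(c(strrep("A", 4), rep("AAAA", 48)))
  m50 <- mini_msa(c(strrep("A", 4), rep("AAAA", 49)))
  expect_false(msa_depth_ok(m49))
  expect_true(msa_depth_ok(m50))
})
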