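# Fixtures are generated in code at test time; nothing is stored on disk.

toy <- function(seed = 1, ...) make_toy_complex(seed = seed, ...)

# Hand-rolled minimal mmCIF writer (test-local) so the mmCIF reader can be
# exercised against an independently produced file, with label_asym_id
# deliberately different from auth_asym_id.
write_mini_cif <- function(complex, path) {
  chains <- list(complex$receptor, complex$peptide)
  labels <- c("AA", "BB")                       # label ids != auth ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_synthetic",
    "#",
    "_pdbx_database_status.recvd_initial_deposition_date 2020-05-01",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num"
  ), con)
  k <- 0
  for (ci in 1:2) {
    ch <- chains[[ci]]
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      k <- k + 1
      writeLines(sprintf(
        "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 0.00 %d %s 1",
        k, a$element[i], a$atom[i], a$resname[i], labels[ci], ci,
        a$seq_index[i], a$x[i], a$y[i], a$z[i], a$resno[i], ch$id), con)
    }
  }
  writeLines("#", con)
  invisible(path)
}

# Write manifests for a list of (native, predicted) complex pairs; returns
# the two manifest paths.
write_pair_manifests <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows_n <- rows_p <- list()
  for (i in seq_along(pairs)) {
    id <- names(pairs)[i] %||% sprintf("cx%02d", i)
    pn <- file.path(dir, paste0(id, "_nat.pdb"))
    pp <- file.path(dir, paste0(id, "_prd.pdb"))
    write_structure(pairs[[i]]$native, pn)
    write_structure(pairs[[i]]$predicted, pp)
    rows_n[[i]] <- data.frame(id = id, path = pn, receptor_chain = "R",
                              peptide_chain = "P")
    rows_p[[i]] <- data.frame(id = id, path = pp, receptor_chain = "R",
                              peptide_chain = "P")
  }
  nm <- file.path(dir, "native.tsv")
  pm <- file.path(dir, "predicted.tsv")
  utils::write.table(do.call(rbind, rows_n), nm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(do.call(rbind, rows_p), pm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(native = nm, predicted = pm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dump the atom table of a complex as TSV for the cross-language oracles.
write_atom_tsv <- function(complex, path) {
  ab <- rbind(cbind(chain = "R", complex$receptor$atoms),
              cbind(chain = "P", complex$peptide$atoms))
  utils::write.table(ab[, c("chain", "seq_index", "atom", "x", "y", "z")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_py_oracle <- function(script, args) {
  out <- suppressWarnings(system2("python",
                                  c(testthat::test_path(script), args),
                                  stdout = TRUE, stderr = FALSE))
  as.numeric(out[length(out)])
}

# Plain-R enumeration oracle for mutual information over two columns
# (independent of column_mi's implementation path).
mi_enumeration_oracle <- function(a, b) {
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  total <- 0
  for (x in unique(a)) for (y in unique(b)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) total <- total + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  total
}
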