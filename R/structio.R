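#' @importFrom bio3d read.pdb write.pdb
NULL

PDB_MONTHS <- c(JAN = 1, FEB = 2, MAR = 3, APR = 4, MAY = 5, JUN = 6,
                JUL = 7, AUG = 8, SEP = 9, OCT = 10, NOV = 11, DEC = 12)

parse_pdb_date <- function(x) {
  # "09-JAN-99" or "09-JAN-1999" -> Date; PDB 2-digit years: <=30 => 20xx
  x <- trimws(x)
  m <- regmatches(x, regexec("^([0-9]{1,2})-([A-Z]{3})-([0-9]{2,4})$", toupper(x)))[[1]]
  if (length(m) != 4 || !(m[3] %in% names(PDB_MONTHS))) return(as.Date(NA))
  yr <- as.integer(m[4])
  if (yr < 100) yr <- if (yr <= 30) 2000L + yr else 1900L + yr
  as.Date(sprintf("%04d-%02d-%02d", yr, PDB_MONTHS[[m[3]]], as.integer(m[2])))
}

format_pdb_date <- function(d) {
  d <- as.Date(d)
  sprintf("%02d-%s-%02d", as.integer(format(d, "%d")),
          names(PDB_MONTHS)[as.integer(format(d, "%m"))],
          as.integer(format(d, "%Y")) %% 100)
}

infer_element <- function(elety, elesy) {
  out <- toupper(trimws(as.character(elesy)))
  miss <- is.na(out) | out == ""
  if (any(miss)) {
    guess <- sub("^[0-9']*", "", toupper(trimws(elety[miss])))
    first2 <- substr(guess, 1, 2)
    e <- substr(guess, 1, 1)
    e[first2 %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")] <-
      first2[first2 %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")]
    out[miss] <- e
  }
  out
}

#' Build a chain object from an atom table
#'
#' Internal constructor shared by the file reader and the synthetic generator.
#' Atoms arrive in file order; residues are numbered `seq_index = 1..n` in
#' that order (author numbering is preserved alongside).
#'
#' @param id chain identifier.
#' @param role `"receptor"` or `"peptide"`.
#' @param atoms data.frame with columns `resno, insert, resname, atom,
#'   element, x, y, z, occupancy, altloc`.
#' @return an object of class `Chain`.
#' @export
chain_from_atoms <- function(id, role, atoms) {
  stopifnot(nrow(atoms) > 0)
  key <- paste(atoms$resno, atoms$insert)
  res_keys <- unique(key)
  atoms$seq_index <- match(key, res_keys)
  res_first <- match(res_keys, key)
  resname <- atoms$resname[res_first]
  code1 <- unname(AA_321[resname])
  code1[is.na(code1)] <- "X"
  structure(list(
    id = id,
    role = role,
    atoms = atoms[, c("seq_index", "resno", "insert", "resname", "atom",
                      "element", "x", "y", "z", "occupancy", "altloc")],
    seq = code1,
    nres = length(res_keys)
  ), class = "Chain")
}

#' Assemble a two-chain protein-peptide complex
#'
#' @param id complex identifier, conventionally `"ENTRY_XY"` where X and Y are
#'   the receptor and peptide chain ids.
#' @param receptor,peptide `Chain` objects with roles `"receptor"` / `"peptide"`.
#' @param release_date a `Date` or `NA` when unknown.
#' @return an object of class `ComplexStructure`.
#' @export
complex_structure <- function(id, receptor, peptide, release_date = as.Date(NA)) {
  stopifnot(inherits(receptor, "Chain"), inherits(peptide, "Chain"))
  if (identical(receptor$id, peptide$id))
    stop("receptor and peptide chain ids must differ")
  for (ch in list(receptor, peptide)) {
    bb <- n_backbone_complete(ch)
    if (bb == 0) stop("chain ", ch$id, " has no backbone-complete residue")
  }
  receptor$role <- "receptor"
  peptide$role <- "peptide"
  structure(list(id = id, receptor = receptor, peptide = peptide,
                 release_date = as.Date(release_date)),
            class = "ComplexStructure")
}

n_backbone_complete <- function(chain) {
  a <- chain$atoms
  has <- tapply(a$atom, a$seq_index, function(nm) all(c("N", "CA", "C", "O") %in% nm))
  sum(has)
}

resolve_altloc <- function(atoms) {
  if (all(atoms$altloc %in% c("", " ", NA))) return(atoms)
  key <- paste(atoms$resno, atoms$insert, atoms$atom)
  keep <- unlist(tapply(seq_len(nrow(atoms)), factor(key, levels = unique(key)),
                        function(idx) {
                          occ <- atoms$occupancy[idx]
                          occ[is.na(occ)] <- 1
                          idx[which.max(occ)]  # ties -> first encountered
                        }))
  atoms[sort(keep), , drop = FALSE]
}

# Header-aware _atom_site reader for mmCIF. Field order varies between
# writers (RCSB, gemmi, ...), so columns are mapped by name.
read_cif_atom_site <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fld_idx <- grep("^_atom_site\\.", lines)
  if (!length(fld_idx)) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[fld_idx]))
  start <- max(fld_idx) + 1
  end <- start
  while (end <= length(lines) &&
         !grepl("^\\s*(#|loop_|_|data_)", lines[end]) &&
         nzchar(trimws(lines[end]))) end <- end + 1
  rows <- lines[start:(end - 1)]
  toks <- scan(text = rows, what = "character", quote = "'\"", quiet = TRUE)
  nf <- length(fields)
  if (length(toks) %% nf != 0) stop("malformed _atom_site loop in ", path)
  m <- matrix(toks, ncol = nf, byrow = TRUE)
  colnames(m) <- fields
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  df[df == "." | df == "?"] <- NA
  df
}

col_or <- function(df, primary, fallback) {
  if (primary %in% names(df)) df[[primary]] else df[[fallback]]
}

# Atom table in the internal layout, from an mmCIF file (first model only).
cif_atoms <- function(path, use_label_ids = FALSE) {
  df <- read_cif_atom_site(path)
  if ("pdbx_PDB_model_num" %in% names(df))
    df <- df[df$pdbx_PDB_model_num == df$pdbx_PDB_model_num[1], , drop = FALSE]
  chain <- if (use_label_ids) col_or(df, "label_asym_id", "auth_asym_id")
           else col_or(df, "auth_asym_id", "label_asym_id")
  data.frame(
    type = df$group_PDB,
    elety = col_or(df, "auth_atom_id", "label_atom_id"),
    alt = df$label_alt_id,
    resid = col_or(df, "auth_comp_id", "label_comp_id"),
    chain = chain,
    resno = as.integer(col_or(df, "auth_seq_id", "label_seq_id")),
    insert = if ("pdbx_PDB_ins_code" %in% names(df)) df$pdbx_PDB_ins_code
             else NA_character_,
    x = as.numeric(df$Cartn_x), y = as.numeric(df$Cartn_y),
    z = as.numeric(df$Cartn_z),
    o = suppressWarnings(as.numeric(df$occupancy)),
    elesy = df$type_symbol,
    stringsAsFactors = FALSE
  )
}

#' Read a two-chain complex from a PDB or mmCIF file
#'
#' Hetero atoms (ligands, waters), hydrogens and alternate conformers beyond
#' the highest-occupancy one are dropped on read; only the first model of a
#' multi-model file is used. The release date is taken from the `HEADER`
#' record (PDB) or `_pdbx_database_status.recvd_initial_deposition_date`
#' (mmCIF) when present.
#'
#' @param path file path; format detected from the `.cif`/`.mmcif` extension.
#' @param receptor_id,peptide_id author chain identifiers of the receptor
#'   (folded protein) and peptide chains.
#' @param id optional complex id; default `"<basename>_<R><P>"`.
#' @param use_label_ids mmCIF only: interpret the chain ids as
#'   `label_asym_id` values and translate them to author ids.
#' @return a [complex_structure()] object.
#' @export
read_structure <- function(path, receptor_id, peptide_id, id = NULL,
                           use_label_ids = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  at <- tryCatch(
    if (is_cif) cif_atoms(path, use_label_ids)
    else suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE))$atom,
    error = function(e) stop("unparseable structure file ", path, ": ",
                             conditionMessage(e)))
  at <- at[at$type == "ATOM", , drop = FALSE]
  at$element <- infer_element(at$elety, at$elesy)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  release <- read_release_date(path, is_cif)

  get_chain <- function(cid, role) {
    sel <- at[at$chain %in% cid, , drop = FALSE]
    if (nrow(sel) == 0) stop("chain '", cid, "' not found in ", path)
    df <- data.frame(
      resno = sel$resno,
      insert = ifelse(is.na(sel$insert), "", sel$insert),
      resname = sel$resid,
      atom = sel$elety,
      element = sel$element,
      x = sel$x, y = sel$y, z = sel$z,
      occupancy = ifelse(is.na(sel$o), 1, sel$o),
      altloc = ifelse(is.na(sel$alt), "", sel$alt),
      stringsAsFactors = FALSE
    )
    df <- resolve_altloc(df)
    ch <- chain_from_atoms(cid, role, df)
    if (n_backbone_complete(ch) == 0)
      stop("chain '", cid, "' has no backbone-complete residue")
    ch
  }
  rec <- get_chain(receptor_id, "receptor")
  pep <- get_chain(peptide_id, "peptide")
  if (is.null(id)) {
    base <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
    id <- paste0(toupper(base), "_", receptor_id, peptide_id)
  }
  complex_structure(id, rec, pep, release)
}

read_release_date <- function(path, is_cif) {
  lines <- readLines(path, n = 200, warn = FALSE)
  if (is_cif) {
    ln <- grep("_pdbx_database_status\\.recvd_initial_deposition_date", lines,
               value = TRUE)
    if (length(ln)) {
      tok <- strsplit(trimws(ln[1]), "[[:space:]]+")[[1]]
      if (length(tok) >= 2) return(suppressWarnings(as.Date(tok[2])))
    }
    return(as.Date(NA))
  }
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) && nchar(hdr[1]) >= 59)
    return(parse_pdb_date(substr(hdr[1], 51, 59)))
  as.Date(NA)
}

#' Write a complex to a PDB file
#'
#' Fixed-column PDB output (via bio3d) with a `HEADER` record carrying the
#' release date when one is set. Round-trips through [read_structure()]
#' preserve coordinates to 1e-3 Angstrom (PDB precision) and residue order
#' exactly.
#'
#' @param complex a `ComplexStructure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(complex, path) {
  stopifnot(inherits(complex, "ComplexStructure"))
  ab <- rbind(cbind(chain = complex$receptor$id, complex$receptor$atoms),
              cbind(chain = complex$peptide$id, complex$peptide$atoms))
  xyz <- as.numeric(t(as.matrix(ab[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(ab)),
    resno = ab$resno, resid = ab$resname,
    eleno = seq_len(nrow(ab)), elety = ab$atom,
    chain = ab$chain, insert = ab$insert,
    o = ab$occupancy, b = rep(0, nrow(ab)),
    elesy = ab$element
  )
  if (!is.na(complex$release_date)) {
    body <- readLines(path, warn = FALSE)
    hdr <- sprintf("HEADER    %-40s%9s   %-4s", "SYNTHETIC COMPLEX",
                   format_pdb_date(complex$release_date), "XXXX")
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Select atom coordinates from a chain
#'
#' @param chain a `Chain`.
#' @param mode `"backbone"` (N, CA, C, O per residue, residue order),
#'   `"heavy"` (all non-hydrogen atoms), `"CA"`, or `"CB_proxy"` (C-beta,
#'   substituting C-alpha for glycine or any residue lacking C-beta).
#' @return list with `xyz` (n x 3 matrix), `residue` (residue `seq_index`
#'   per selected atom), `atom` (atom names) and `skipped` (indices of
#'   residues lacking the required atoms, excluded from the selection).
#' @export
select_atoms <- function(chain, mode = c("backbone", "heavy", "CA", "CB_proxy")) {
  mode <- match.arg(mode)
  a <- chain$atoms
  skipped <- integer(0)
  if (mode == "heavy") {
    sel <- a
  } else if (mode == "CA") {
    sel <- a[a$atom == "CA", , drop = FALSE]
    skipped <- setdiff(seq_len(chain$nres), sel$seq_index)
  } else if (mode == "CB_proxy") {
    rows <- integer(0)
    for (ri in seq_len(chain$nres)) {
      idx <- which(a$seq_index == ri)
      cb <- idx[a$atom[idx] == "CB"]
      ca <- idx[a$atom[idx] == "CA"]
      pick <- if (length(cb)) cb[1] else if (length(ca)) ca[1] else NA_integer_
      if (is.na(pick)) skipped <- c(skipped, ri) else rows <- c(rows, pick)
    }
    sel <- a[rows, , drop = FALSE]
  } else {
    rows <- integer(0)
    for (ri in seq_len(chain$nres)) {
      idx <- which(a$seq_index == ri)
      want <- match(c("N", "CA", "C", "O"), a$atom[idx])
      if (anyNA(want)) skipped <- c(skipped, ri)
      else rows <- c(rows, idx[want])
    }
    sel <- a[rows, , drop = FALSE]
  }
  list(xyz = unname(as.matrix(sel[, c("x", "y", "z")])),
       residue = sel$seq_index, atom = sel$atom, skipped = skipped)
}

#' One-letter amino-acid sequence of a chain
#'
#' Non-standard residues map to `"X"`.
#' @param chain a `Chain`.
#' @return a single character string, one letter per residue.
#' @export
chain_sequence <- function(chain) paste(chain$seq, collapse = "")

#' @export
print.ComplexStructure <- function(x, ...) {
  cat(sprintf("ComplexStructure %s: receptor %s (%d res), peptide %s (%d res), released %s\n",
              x$id, x$receptor$id, x$receptor$nres, x$peptide$id, x$peptide$nres,
              ifelse(is.na(x$release_date), "unknown", format(x$release_date))))
  invisible(x)
}

#' @export
print.Chain <- function(x, ...) {
  cat(sprintf("Chain %s (%s): %d residues, %d atoms\n", x$id, x$role, x$nres,
              nrow(x$atoms)))
  invisible(x)
}

# Transform every atom of a chain: xyz %*% rotation + translation.
transform_chain <- function(chain, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  new <- xyz %*% rotation + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  chain$atoms$x <- new[, 1]; chain$atoms$y <- new[, 2]; chain$atoms$z <- new[, 3]
  chain
}
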