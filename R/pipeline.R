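# Batch orchestration: evaluate many native/predicted pairs into a metrics
# table, compare conditions with standard rank tests, and summarize
# accuracy as a function of confidence.

read_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "receptor_chain", "peptide_chain")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0) stop("empty manifest: ", path)
  if (anyDuplicated(tab$id)) stop("duplicate ids in manifest: ", path)
  tab
}

#' Evaluate a batch of predictions against their natives
#'
#' Computes the full metric panel per (native, predicted) pair: Fnat,
#' iRMSD, LRMSD, DockQ + category, atomic accuracy, receptor TM-score and
#' peptide RMSD; optionally RMSD_map (when both manifests carry a
#' `distogram` column) and confidence summaries (when the predicted
#' manifest carries a `confidence` column pointing at a JSON record).
#' Per-complex failures are logged to standard error and flagged in the
#' `error` column; the batch continues.
#'
#' @param native_manifest,predicted_manifest TSV paths with columns `id`,
#'   `path`, `receptor_chain`, `peptide_chain` (+ optional `distogram`,
#'   `confidence`); the two manifests are joined on `id`.
#' @param condition label stored in the `condition` column.
#' @return a data.frame (one row per id x condition) of class
#'   `metrics_table`.
#' @export
evaluate_batch <- function(native_manifest, predicted_manifest,
                           condition = "default") {
  nat <- read_manifest(native_manifest)
  prd <- read_manifest(predicted_manifest)
  ids <- nat$id
  if (!setequal(ids, prd$id))
    stop("native and predicted manifests must carry the same ids")
  prd <- prd[match(ids, prd$id), , drop = FALSE]

  rows <- lapply(seq_along(ids), function(i) {
    base <- data.frame(
      id = ids[i], condition = condition,
      fnat = NA_real_, irmsd = NA_real_, lrmsd = NA_real_,
      dockq = NA_real_, category = NA_character_, atomic_pass = NA,
      tm_score = NA_real_, peptide_rmsd = NA_real_, rmsd_map = NA_real_,
      ranking_confidence = NA_real_, ipae = NA_real_, pdockq = NA_real_,
      error = "", stringsAsFactors = FALSE
    )
    out <- tryCatch({
      native <- read_structure(nat$path[i], nat$receptor_chain[i],
                               nat$peptide_chain[i])
      predicted <- read_structure(prd$path[i], prd$receptor_chain[i],
                                  prd$peptide_chain[i])
      dq <- dockq(native, predicted)
      aa <- atomic_accuracy(native, predicted)
      base$fnat <- dq$fnat; base$irmsd <- dq$irmsd; base$lrmsd <- dq$lrmsd
      base$dockq <- dq$score; base$category <- dq$category
      base$atomic_pass <- aa$passed
      base$tm_score <- tm_score(native$receptor, predicted$receptor)
      base$peptide_rmsd <- peptide_rmsd_after_protein_alignment(native, predicted)
      if (all(c("distogram") %in% names(nat)) && "distogram" %in% names(prd) &&
          nzchar(nat$distogram[i]) && nzchar(prd$distogram[i])) {
        rm <- rmsd_map(read_distogram(nat$distogram[i]),
                       read_distogram(prd$distogram[i]))
        base$rmsd_map <- rm$value
      }
      if ("confidence" %in% names(prd) && nzchar(prd$confidence[i])) {
        rec <- read_confidence_json(prd$confidence[i])
        cs <- confidence_summary(rec, predicted)
        base$ranking_confidence <- cs$ranking_confidence
        base$ipae <- cs$ipae
        base$pdockq <- cs$pdockq
      }
      base
    }, error = function(e) {
      message("evaluate_batch: ", ids[i], " failed: ", conditionMessage(e))
      base$error <- conditionMessage(e)
      base
    })
    out
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("metrics_table", class(tab))
  tab
}

#' Write a metrics table as TSV
#'
#' Deterministic output: fixed column order, full-precision numerics.
#'
#' @param table a metrics table from [evaluate_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  utils::write.table(format(as.data.frame(table), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare a metric between two conditions
#'
#' Wilcoxon signed-rank test for paired designs (identical id sets) or a
#' two-sided Mann-Whitney U test for unpaired ones, delegated to
#' [stats::wilcox.test()].
#'
#' @param table a metrics table.
#' @param metric column name to compare.
#' @param condition_a,condition_b condition labels.
#' @param paired logical; paired requires identical id sets in both
#'   conditions.
#' @return list of class `ComparisonResult`: `test_name`, `statistic`,
#'   `p_value`, `n`, `paired`.
#' @export
compare_conditions <- function(table, metric, condition_a, condition_b,
                               paired = FALSE) {
  ta <- table[table$condition == condition_a, , drop = FALSE]
  tb <- table[table$condition == condition_b, , drop = FALSE]
  if (paired) {
    if (!setequal(ta$id, tb$id))
      stop("paired comparison requires identical id sets")
    tb <- tb[match(ta$id, tb$id), , drop = FALSE]
  }
  a <- ta[[metric]]; b <- tb[[metric]]
  keep <- !is.na(a) & if (paired) !is.na(b) else TRUE
  a <- a[keep]
  b <- if (paired) b[keep] else b[!is.na(b)]
  n <- if (paired) length(a) else min(length(a), length(b))
  if (n < 5) stop("refusing to test with fewer than 5 observations per group")
  wt <- suppressWarnings(
    if (paired) stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    else stats::wilcox.test(a, b, paired = FALSE, exact = FALSE)
  )
  structure(list(
    test_name = if (paired) "wilcoxon_signed_rank" else "mann_whitney_u",
    statistic = unname(wt$statistic),
    p_value = if (is.nan(wt$p.value)) 1 else wt$p.value,
    n = n, paired = paired
  ), class = "ComparisonResult")
}

#' Adjust a set of comparison p-values
#'
#' Benjamini-Hochberg adjustment via [stats::p.adjust()]; intended when
#' more than a handful of comparisons are reported together.
#'
#' @param comparisons list of `ComparisonResult` objects.
#' @return data.frame with `test_name`, `p_value` and `p_adjusted_bh`.
#' @export
adjust_comparisons <- function(comparisons) {
  p <- vapply(comparisons, `[[`, numeric(1), "p_value")
  data.frame(test_name = vapply(comparisons, `[[`, character(1), "test_name"),
             p_value = p, p_adjusted_bh = stats::p.adjust(p, "BH"))
}

#' Summarize a metrics table
#'
#' Medians per numeric metric, the fraction of rows in each DockQ category,
#' the fraction atomically accurate, and — for each confidence cutoff — the
#' fraction of rows with ranking confidence above the cutoff whose DockQ
#' exceeds each category threshold (the cumulative confidence-vs-accuracy
#' view).
#'
#' @param table a metrics table.
#' @param confidence_cutoffs numeric cutoffs on `ranking_confidence`.
#' @return list with `medians`, `category_fractions`, `fraction_atomic`,
#'   and `by_confidence` (data.frame, one row per cutoff).
#' @export
summarize_metrics <- function(table, confidence_cutoffs = c(0.5, 0.75, 0.9)) {
  if (nrow(table) == 0) stop("empty metrics table")
  ok <- table[!nzchar(table$error %||% ""), , drop = FALSE]
  num_cols <- intersect(c("fnat", "irmsd", "lrmsd", "dockq", "tm_score",
                          "peptide_rmsd", "rmsd_map", "ranking_confidence",
                          "ipae", "pdockq"), names(ok))
  medians <- vapply(num_cols, function(cn)
    stats::median(ok[[cn]], na.rm = TRUE), numeric(1))
  cats <- factor(ok$category, levels = c("poor", "acceptable", "medium", "high"))
  cat_frac <- table(cats) / sum(!is.na(cats))
  by_conf <- NULL
  if (any(!is.na(ok$ranking_confidence))) {
    by_conf <- do.call(rbind, lapply(confidence_cutoffs, function(cc) {
      sel <- ok[!is.na(ok$ranking_confidence) & ok$ranking_confidence > cc, ,
                drop = FALSE]
      data.frame(cutoff = cc, n = nrow(sel),
                 frac_acceptable = mean(sel$dockq > 0.23),
                 frac_medium = mean(sel$dockq > 0.49),
                 frac_high = mean(sel$dockq > 0.80))
    }))
  }
  list(medians = medians,
       category_fractions = as.numeric(cat_frac),
       category_levels = levels(cats),
       fraction_atomic = mean(ok$atomic_pass, na.rm = TRUE),
       by_confidence = by_conf)
}
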