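# VAF-based clonality comparison across regional categories, and
# recurrence tabulation of cancer-list genes.

#' Variant allele frequency of records
#'
#' `alt / (alt + ref)` read depths. Records missing either depth, or with
#' zero total depth, yield `NA` (callers count and report them).
#'
#' @param records mutation set rows.
#' @return numeric vector of VAFs in `[0, 1]` (with `NA`s).
#' @export
vaf <- function(records) {
  tot <- records$alt_depth + records$ref_depth
  out <- ifelse(!is.na(tot) & tot > 0, records$alt_depth / tot, NA_real_)
  as.numeric(out)
}

# Mann-Whitney U, two-sided, normal approximation with tie correction.
# Degenerate case (zero variance, i.e. all observations equal) -> p = 1.
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
  p <- if (!is.finite(z)) 1 else 2 * stats::pnorm(-abs(z))
  list(U = u1, p_value = min(p, 1))
}

#' Compare VAF distributions across regional categories
#'
#' Groups every record with a usable VAF into four strata -- primary-specific,
#' CTC-specific, common-in-primary and common-in-CTC (a shared mutation
#' contributes each lesion's own measurement to that lesion's comparison) --
#' then summarizes each stratum and tests lesion-specific vs common within
#' each lesion with a two-sided Mann-Whitney U (normal approximation, tie
#' corrected). P-values are raw; no multiplicity correction is applied.
#'
#' @param classified_records output of [annotate_categories()], possibly
#'   row-bound over a cohort.
#' @return list with `summary` (per-group n, median, IQR), `tests`
#'   (comparison, U, p, or skip reason) and `n_skipped_records` (records
#'   without usable depths).
#' @export
compare_vaf_by_category <- function(classified_records) {
  rec <- as.data.table(classified_records)
  need <- c("lesion", "category")
  if (!all(need %in% names(rec)))
    stop("records must carry lesion and category columns")
  rec[, vaf_value := vaf(rec)]
  n_skip <- sum(is.na(rec$vaf_value))
  rec <- rec[!is.na(vaf_value)]
  rec[, group := ifelse(category == "common",
                        paste0("common_", lesion), category)]
  summary <- rec[, .(n = .N, median_vaf = median(vaf_value),
                     q1 = quantile(vaf_value, 0.25),
                     q3 = quantile(vaf_value, 0.75)),
                 by = group][order(group)]
  comparisons <- list(
    c("primary_specific", "common_primary"),
    c("ctc_specific", "common_ctc"))
  tests <- rbindlist(lapply(comparisons, function(cp) {
    x <- rec[group == cp[1], vaf_value]
    y <- rec[group == cp[2], vaf_value]
    if (!length(x) || !length(y))
      return(data.table(group1 = cp[1], group2 = cp[2], n1 = length(x),
                        n2 = length(y), U = NA_real_, p_value = NA_real_,
                        skipped = "empty group"))
    mw <- mann_whitney(x, y)
    data.table(group1 = cp[1], group2 = cp[2], n1 = length(x),
               n2 = length(y), U = mw$U, p_value = mw$p_value,
               skipped = NA_character_)
  }))
  list(summary = summary, tests = tests, n_skipped_records = n_skip)
}

#' Recurrently mutated cancer-list genes per regional category
#'
#' For each gene on the supplied list and each regional category, counts
#' the number of distinct cases carrying at least one mutation of that gene
#' in that category (per case, not per mutation), with a consequence
#' breakdown. Genes reaching `min_cases` in a category are reported; an
#' across-category case count is emitted alongside since reporting
#' conventions differ.
#'
#' @param classified_records [annotate_categories()] output row-bound over
#'   the cohort (must carry `case_id`, `gene`, `category`, `func_class`,
#'   `key`).
#' @param gene_list character vector of gene symbols; others are ignored.
#' @param min_cases recurrence threshold (default 3).
#' @return `data.table` with columns gene, category, n_cases, n_missense,
#'   n_nonsense, n_other, n_total_cases (distinct cases in any category).
#' @export
recurrent_gene_table <- function(classified_records, gene_list,
                                 min_cases = 3L) {
  if (!length(gene_list)) stop("gene_list must be non-empty")
  rec <- as.data.table(classified_records)
  rec <- rec[!is.na(gene) & gene %in% gene_list]
  if (!nrow(rec))
    return(data.table(gene = character(), category = character(),
                      n_cases = integer(), n_missense = integer(),
                      n_nonsense = integer(), n_other = integer(),
                      n_total_cases = integer()))
  # one row per distinct mutation per case/category (common appears per
  # lesion in the input; collapse so consequences are counted once)
  mut <- unique(rec, by = c("case_id", "category", "key"))
  tab <- mut[, .(
    n_cases = uniqueN(case_id),
    n_missense = sum(func_class == "missense", na.rm = TRUE),
    n_nonsense = sum(func_class == "nonsense", na.rm = TRUE),
    n_other = sum(!func_class %in% c("missense", "nonsense") |
                    is.na(func_class))),
    by = .(gene, category)]
  totals <- mut[, .(n_total_cases = uniqueN(case_id)), by = gene]
  tab <- merge(tab, totals, by = "gene")
  tab <- tab[n_cases >= min_cases][order(-n_cases, gene, category)]
  tab[]
}
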