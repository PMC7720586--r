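# Regional classification and concordance statistics for a paired callset.

#' Partition a case's mutations into regional categories
#'
#' Exact set algebra on mutation keys: `common` is the intersection of the
#' two lesions' key sets, `primary_specific` and `ctc_specific` the set
#' differences. The three sets are disjoint and their union is the union of
#' both lesions' keys.
#'
#' @param pair a [paired_callset()].
#' @return object of class `regional_classification` with character-vector
#'   slots `common`, `primary_specific`, `ctc_specific`.
#' @export
classify_regional <- function(pair) {
  stopifnot(inherits(pair, "paired_callset"))
  kp <- mutation_keys(pair$primary)
  kc <- mutation_keys(pair$ctc)
  structure(list(case_id = pair$case_id,
                 common = intersect(kp, kc),
                 primary_specific = setdiff(kp, kc),
                 ctc_specific = setdiff(kc, kp)),
            class = "regional_classification")
}

#' @export
print.regional_classification <- function(x, ...) {
  cat(sprintf(
    "<regional_classification> case %s: %d common, %d primary-specific, %d ctc-specific\n",
    x$case_id, length(x$common), length(x$primary_specific),
    length(x$ctc_specific)))
  invisible(x)
}

#' Attach regional categories to a case's records
#'
#' Long view of a paired callset with a `category` column. Common mutations
#' appear twice -- once per lesion, each with its own depths -- so every
#' per-lesion quantity (such as VAF) stays attached to the lesion that
#' measured it.
#'
#' @param pair a [paired_callset()].
#' @param classification its [classify_regional()] result (recomputed when
#'   omitted).
#' @return `data.table` of records with `category` in
#'   `{common, primary_specific, ctc_specific}`.
#' @export
annotate_categories <- function(pair, classification = NULL) {
  if (is.null(classification)) classification <- classify_regional(pair)
  all_rec <- rbind(pair$primary, pair$ctc)
  k <- mutation_keys(all_rec)
  cat_ <- rep("common", nrow(all_rec))
  cat_[k %in% classification$primary_specific] <- "primary_specific"
  cat_[k %in% classification$ctc_specific] <- "ctc_specific"
  all_rec[, key := k]
  all_rec[, category := cat_]
  all_rec[]
}

#' Concordance fraction of a classified case
#'
#' `|common| / |denominator|`. The default denominator is the union of both
#' lesions' mutations; per-lesion denominators (`"primary"` = common +
#' primary-specific, `"ctc"` analogously) are also available because the
#' reporting convention for "fraction of mutations in a case" is ambiguous.
#'
#' @param classification a [classify_regional()] result.
#' @param denominator `"union"`, `"primary"` or `"ctc"`.
#' @return fraction in `[0, 1]`.
#' @export
concordance_fraction <- function(classification,
                                 denominator = c("union", "primary", "ctc")) {
  denominator <- match.arg(denominator)
  n_common <- length(classification$common)
  n_p <- length(classification$primary_specific)
  n_c <- length(classification$ctc_specific)
  denom <- switch(denominator,
                  union = n_common + n_p + n_c,
                  primary = n_common + n_p,
                  ctc = n_common + n_c)
  if (denom == 0)
    stop("empty ", denominator, " denominator for case ",
         classification$case_id, "; concordance undefined")
  n_common / denom
}

#' Per-case abundance and concordance summary for a cohort
#'
#' @param pairs list of [paired_callset()].
#' @return `data.table` with one row per case: lesion abundances, counts of
#'   the three regional categories, and concordance under all three
#'   denominators (as fractions; multiply by 100 for percent).
#' @export
cohort_concordance_table <- function(pairs) {
  rbindlist(lapply(pairs, function(pair) {
    cls <- classify_regional(pair)
    data.table(
      case_id = pair$case_id,
      n_primary = nrow(pair$primary),
      n_ctc = nrow(pair$ctc),
      n_common = length(cls$common),
      n_primary_specific = length(cls$primary_specific),
      n_ctc_specific = length(cls$ctc_specific),
      concordance_union = concordance_fraction(cls, "union"),
      concordance_primary = concordance_fraction(cls, "primary"),
      concordance_ctc = concordance_fraction(cls, "ctc"))
  }))
}

#' Correlation of per-case mutation abundance between lesions
#'
#' Pearson product-moment correlation (two-sided p from the t transform
#' with n-2 degrees of freedom) of total exonic mutation counts -- SNVs and
#' indels -- between primary and CTC callsets. A Spearman option exists for
#' sensitivity analysis.
#'
#' @param pairs list of [paired_callset()] (>= 3 cases).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `p_value`, `n`, and the two abundance vectors.
#' @export
abundance_correlation <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(pairs) < 3L)
    stop("abundance correlation needs at least 3 cases")
  x <- vapply(pairs, function(p) nrow(p$primary), 1L)
  y <- vapply(pairs, function(p) nrow(p$ctc), 1L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("abundance has zero variance in one lesion; correlation undefined")
  ct <- cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       primary_totals = x, ctc_totals = y)
}
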