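# Functional consequences, mutation spectra, signature refitting and
# exposure clustering.

#' Functional-consequence proportions and NS/S ratios per category
#'
#' Tabulates the share of each functional class within each regional
#' category and the ratio of missense (nonsynonymous) to silent mutations.
#' NS/S ratios near or above 2 are the classic sanity check that a callset
#' is dominated by somatic rather than germline variation.
#'
#' @param records classified records from [annotate_categories()] (or any
#'   table with `func_class` and `category` columns). Common mutations
#'   appearing once per lesion are de-duplicated by key so each mutation is
#'   counted once.
#' @param ns_numerator `"missense"` (default) or `"missense+nonsense"`.
#' @return list with `proportions` (category x func_class `data.table`) and
#'   `ns_s` (named vector of ratios; `NA` when a category has no silent
#'   mutations).
#' @export
consequence_table <- function(records,
                              ns_numerator = c("missense",
                                               "missense+nonsense")) {
  ns_numerator <- match.arg(ns_numerator)
  records <- as.data.table(records)
  if (!"category" %in% names(records))
    stop("records must carry a 'category' column (see annotate_categories)")
  if ("key" %in% names(records))
    records <- unique(records, by = c("case_id", "key", "category"))
  counts <- dcast(
    records[!is.na(func_class),
            .N, by = .(category, func_class)],
    category ~ func_class, value.var = "N", fill = 0L)
  for (fc in setdiff(FUNC_CLASSES, names(counts))) counts[, (fc) := 0L]
  setcolorder(counts, c("category", FUNC_CLASSES))
  prop <- copy(counts)
  tot <- rowSums(prop[, FUNC_CLASSES, with = FALSE])
  for (fc in FUNC_CLASSES) prop[, (fc) := get(fc) / tot]
  num <- counts$missense +
    if (ns_numerator == "missense+nonsense") counts$nonsense else 0L
  ns_s <- ifelse(counts$silent > 0, num / counts$silent, NA_real_)
  names(ns_s) <- counts$category
  list(counts = counts[], proportions = prop[], ns_s = ns_s)
}

#' Mutation spectrum over 6 or 96 classes
#'
#' Counts single-nucleotide substitutions after collapsing onto the
#' pyrimidine strand. Indels always lack a spectrum class and are skipped;
#' for the 96-class spectrum, SNVs without a trinucleotide context are
#' skipped too. Skips are counted, never silent.
#'
#' @param records mutation set rows.
#' @param n_classes 6 or 96.
#' @param normalize return proportions instead of counts (error on an
#'   all-zero spectrum).
#' @return object of class `spectrum` -- a list with `counts` (named
#'   vector), `n_used`, `n_skipped`, and `empty` flag.
#' @export
mutation_spectrum <- function(records, n_classes = 6L, normalize = FALSE) {
  if (!n_classes %in% c(6L, 96L)) stop("n_classes must be 6 or 96")
  records <- as.data.table(records)
  is_snv <- if (nrow(records)) nchar(records$ref) == 1L &
    nchar(records$alt) == 1L else logical(0)
  usable <- is_snv
  if (n_classes == 96L)
    usable <- usable & !is.na(records$context) & nzchar(records$context)
  n_skipped <- nrow(records) - sum(usable)
  labels <- if (n_classes == 6L) SUBSTITUTION_CLASSES else
    context_labels_96()
  counts <- setNames(numeric(length(labels)), labels)
  if (any(usable)) {
    rec <- records[which(usable)]
    coll <- collapse_strand(rec$ref, rec$alt,
                            if (n_classes == 96L) rec$context else
                              rec$context)
    lab <- if (n_classes == 6L) coll$class else
      context_label(coll$class, coll$context)
    tab <- table(lab)
    counts[names(tab)] <- as.numeric(tab)
  }
  out <- structure(list(counts = counts, n_classes = n_classes,
                        n_used = sum(usable), n_skipped = n_skipped,
                        empty = sum(counts) == 0),
                   class = "spectrum")
  if (normalize) {
    if (out$empty) stop("cannot normalize an all-zero spectrum")
    out$counts <- out$counts / sum(out$counts)
  }
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d classes, %d mutations used, %d skipped%s\n",
              x$n_classes, x$n_used, x$n_skipped,
              if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Refit signature exposures to a 96-class spectrum
#'
#' Solves `min || S e - v ||_2` subject to `e >= 0`, where the columns of
#' `S` are the catalog signatures and `v` the observed 96-class count
#' vector: standard signature refitting against a fixed catalog (no de novo
#' extraction). Exposures are reported in mutation-count units and as
#' proportions of their sum, with the reconstruction residual and cosine
#' similarity.
#'
#' @param spectrum96 a [mutation_spectrum()] result with 96 classes, or a
#'   named 96-vector of counts.
#' @param catalog catalog matrix (see [read_signature_catalog()]).
#' @param low_confidence_below flag exposures fitted on fewer SNVs than
#'   this as low-confidence (refitting is unstable on sparse spectra).
#' @return object of class `exposure_fit`: `exposures`, `proportions`,
#'   `residual` (L2 norm), `cosine`, `n_mutations`, `low_confidence`.
#' @export
refit_exposures <- function(spectrum96, catalog,
                            low_confidence_below = 50) {
  catalog <- validate_catalog(catalog)
  v <- if (inherits(spectrum96, "spectrum")) {
    if (spectrum96$n_classes != 96L)
      stop("refitting needs the 96-class spectrum")
    spectrum96$counts
  } else spectrum96
  if (length(v) != 96L) stop("spectrum must have 96 entries")
  if (!is.null(names(v))) v <- v[rownames(catalog)]
  if (anyNA(v) || any(v < 0)) stop("spectrum counts must be non-negative")
  if (sum(v) == 0) stop("cannot refit an all-zero spectrum")
  fit <- nnls_solve(catalog, v)
  e <- setNames(fit$x, colnames(catalog))
  recon <- as.numeric(catalog %*% e)
  structure(list(
    exposures = e,
    proportions = if (sum(e) > 0) e / sum(e) else e,
    residual = sqrt(fit$deviance),
    cosine = cosine_sim(v, recon),
    n_mutations = sum(v),
    low_confidence = sum(v) < low_confidence_below),
    class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("<exposure_fit> %d mutations, cosine %.4f%s\n",
              round(x$n_mutations), x$cosine,
              if (x$low_confidence) " [low confidence]" else ""))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Hierarchically cluster exposure profiles
#'
#' Average-linkage agglomerative clustering on Euclidean distances between
#' proportion-normalized exposure profiles. Profiles are sorted by label
#' before clustering so ties break deterministically.
#'
#' @param exposure_matrix numeric matrix, rows = profiles (categories or
#'   cases), columns = signatures; rows are renormalized to proportions.
#' @param normalize renormalize rows to sum 1 (default `TRUE`).
#' @return list with `hclust` (the merge tree), `order` (leaf labels in
#'   dendrogram order) and `newick` (the tree serialized as a Newick
#'   string).
#' @export
cluster_exposures <- function(exposure_matrix, normalize = TRUE) {
  m <- as.matrix(exposure_matrix)
  if (nrow(m) < 2L) stop("clustering needs at least 2 profiles")
  if (is.null(rownames(m))) rownames(m) <- sprintf("profile%02d",
                                                   seq_len(nrow(m)))
  m <- m[order(rownames(m)), , drop = FALSE]
  if (normalize) {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("cannot normalize an all-zero profile")
    m <- m / rs
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}
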