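# Shared fixtures and independent oracles used across test files.

library(data.table)

# quick mutation-set constructor; pos doubles as the identity
mk_records <- function(case_id, lesion, pos,
                       ref = "C", alt = "T", chrom = "1",
                       gene = NA_character_, func_class = NA_character_,
                       context = NA_character_,
                       alt_depth = NA_integer_, ref_depth = NA_integer_) {
  data.table(case_id = case_id, lesion = lesion, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
             func_class = func_class, context = context,
             alt_depth = as.integer(alt_depth),
             ref_depth = as.integer(ref_depth))
}

# random SNV set with valid contexts (keys unique within the set)
random_mutation_set <- function(n, case_id = "C1", lesion = "primary",
                                with_depths = FALSE) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  ctx <- paste0(sample(bases, n, TRUE), ref, sample(bases, n, TRUE))
  mk_records(case_id, lesion, pos = sample.int(1e7, n), ref = ref,
             alt = alt, context = ctx,
             func_class = sample(c("missense", "silent", "nonsense",
                                   "other"), n, TRUE),
             gene = sample(sprintf("G%02d", 1:20), n, TRUE),
             alt_depth = if (with_depths)
               sample(1:60, n, TRUE) else NA_integer_,
             ref_depth = if (with_depths)
               sample(1:60, n, TRUE) else NA_integer_)
}

# a single-signature catalog with all mass spread over the 16 C>T contexts
pure_ct_catalog <- function() {
  labels <- context_labels_96()
  v <- numeric(96)
  v[grepl("\\[C>T\\]", labels)] <- 1 / 16
  m <- matrix(v, ncol = 1, dimnames = list(labels, "PURE_CT"))
  m
}

toy_catalog <- function() {
  read_signature_catalog(system.file("extdata", "toy_signatures.tsv",
                                     package = "ctcmut"))
}

table1_path <- function()
  system.file("extdata", "cohort_table1.tsv", package = "ctcmut")

# O(n^3) average-linkage agglomeration, independent of stats::hclust:
# returns the sorted sequence of merge heights
brute_average_linkage_heights <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters <- c(clusters, list(merged))
  }
  heights
}

# small three-case cohort with hand-computable set algebra:
#   case A: primary {1,2,3}, ctc {2,3,4} -> common 2, union 4
#   case B: primary {10,11}, ctc {10,11} -> common 2, union 2
#   case C: primary {20},    ctc {21}    -> common 0, union 2
hand_cohort <- function() {
  list(
    paired_callset("A", mk_records("A", "primary", 1:3),
                   mk_records("A", "ctc", 2:4)),
    paired_callset("B", mk_records("B", "primary", 10:11),
                   mk_records("B", "ctc", 10:11)),
    paired_callset("C", mk_records("C", "primary", 20),
                   mk_records("C", "ctc", 21)))
}

fast_sim_config <- function(n_cases = 3L, ...) {
  sim_config(n_cases = n_cases, trunk_bounds = c(10L, 40L),
             branch_bounds_primary = c(20L, 80L),
             branch_bounds_ctc = c(20L, 80L), ...)
}

# data.table() treats a 'key' argument specially; build it afterwards
dt_with_key <- function(..., key_col) {
  dt <- data.table(...)
  dt[, key := key_col]
  dt[]
}
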