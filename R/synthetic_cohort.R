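# Trunk-branch synthetic cohort generator.
#
# Each case carries one clonal trunk (mutations present in both lesions)
# and two private branches (primary-only, CTC-only). Trinucleotide contexts
# are drawn from category-specific signature mixtures, true allele
# frequencies from category-specific Beta distributions, and detection in a
# lesion requires >= min_alt_reads alternate reads at a Poisson depth plus
# an independent Bernoulli sensitivity. The closed-form twin
# expected_concordance() predicts the cohort-mean concordance and serves as
# the simulator's oracle.

#' Build a simulation configuration
#'
#' Defaults state the cohort the generator emulates: 20 cases, per-lesion
#' exonic mutation burdens roughly log-uniform between tens and ~1500
#' (trunk 10-150 plus branch 20-1400), APOBEC-weighted primary-specific
#' contexts, C>T-enriched / C>G-free CTC-specific contexts, clonal-high
#' Beta allele frequencies for lesion-specific mutations and lower ones for
#' shared mutations, ~100x mean depth with a 3-alt-read detection floor.
#'
#' @param n_cases number of simulated cases.
#' @param trunk_bounds integer bounds of the log-uniform trunk size.
#' @param branch_bounds_primary,branch_bounds_ctc bounds of the log-uniform
#'   private-branch sizes.
#' @param catalog signature catalog matrix (96 x k); defaults to the
#'   packaged toy catalog.
#' @param signature_mix named list with elements `common`,
#'   `primary_specific`, `ctc_specific`, each a named non-negative weight
#'   vector over catalog signatures summing to 1.
#' @param vaf_beta named list mapping the same three categories to
#'   `c(alpha, beta)` of the true-VAF Beta distribution.
#' @param depth_mean mean Poisson sequencing depth per mutation per lesion.
#' @param min_alt_reads minimum alternate reads for a call to be detected.
#' @param detect_prob extra per-lesion per-mutation Bernoulli sensitivity.
#' @param func_class_probs named probabilities over functional classes;
#'   the `indel` mass generates length-changing alleles without context.
#' @param strand_flip_prob probability a simulated SNV is reported on the
#'   purine strand (exercises strand collapsing downstream).
#' @param gene_pool gene symbols assigned uniformly to mutations.
#' @param seed base seed; per-case streams derive from it.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 20L,
                       trunk_bounds = c(10L, 150L),
                       branch_bounds_primary = c(20L, 1400L),
                       branch_bounds_ctc = c(20L, 1400L),
                       catalog = default_catalog(),
                       signature_mix = list(
                         common = c(FLAT = 0.5, CpG = 0.3,
                                    CG_TRANSVERSION = 0.2),
                         primary_specific = c(APOBEC = 0.6, FLAT = 0.4),
                         ctc_specific = c(CT_ENRICHED = 0.7, FLAT = 0.3)),
                       vaf_beta = list(common = c(2, 8),
                                       primary_specific = c(5, 5),
                                       ctc_specific = c(5, 5)),
                       depth_mean = 100,
                       min_alt_reads = 3L,
                       detect_prob = 1,
                       func_class_probs = c(missense = 0.50, silent = 0.20,
                                            nonsense = 0.05, splice = 0.03,
                                            indel = 0.12, other = 0.10),
                       strand_flip_prob = 0.5,
                       gene_pool = sprintf("GENE%03d", 1:300),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d cases, trunk %d-%d, branches %d-%d",
                     " / %d-%d, depth %g, min_alt %d, detect_prob %g\n"),
              x$n_cases, x$trunk_bounds[1], x$trunk_bounds[2],
              x$branch_bounds_primary[1], x$branch_bounds_primary[2],
              x$branch_bounds_ctc[1], x$branch_bounds_ctc[2],
              x$depth_mean, x$min_alt_reads, x$detect_prob))
  invisible(x)
}

#' The packaged toy signature catalog
#'
#' Five synthetic signatures: an APOBEC-like TpC signature, a CpG
#' deamination signature, a flat background, a C>T-enriched / C>G-free
#' signature, and a C>G transversion signature.
#'
#' @return 96 x 5 catalog matrix.
#' @export
default_catalog <- function() {
  read_signature_catalog(system.file("extdata", "toy_signatures.tsv",
                                     package = "ctcmut", mustWork = TRUE))
}

SIM_CATEGORIES <- c("common", "primary_specific", "ctc_specific")

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n_cases), cfg$n_cases >= 1)
  for (b in list(cfg$trunk_bounds, cfg$branch_bounds_primary,
                 cfg$branch_bounds_ctc)) {
    if (length(b) != 2L || any(b <= 0) || b[1] > b[2])
      stop("count bounds must be positive and ordered (lo <= hi)")
  }
  cfg$catalog <- validate_catalog(cfg$catalog)
  if (!setequal(names(cfg$signature_mix), SIM_CATEGORIES))
    stop("signature_mix must name categories: ",
         paste(SIM_CATEGORIES, collapse = ", "))
  for (cat_ in SIM_CATEGORIES) {
    w <- cfg$signature_mix[[cat_]]
    if (is.null(names(w)) || !all(names(w) %in% colnames(cfg$catalog)))
      stop("signature_mix[", cat_, "] names must match catalog signatures")
    if (any(w < 0)) stop("signature weights must be non-negative")
    if (abs(sum(w) - 1) > 1e-9)
      stop("signature_mix[", cat_, "] must sum to 1 within 1e-9")
    ab <- cfg$vaf_beta[[cat_]]
    if (is.null(ab) || length(ab) != 2L || any(ab <= 0))
      stop("vaf_beta[", cat_, "] must be positive (alpha, beta)")
  }
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (cfg$min_alt_reads < 0) stop("min_alt_reads must be >= 0")
  if (cfg$detect_prob < 0 || cfg$detect_prob > 1)
    stop("detect_prob must lie in [0, 1]")
  p <- cfg$func_class_probs
  if (is.null(names(p)) || !all(names(p) %in% FUNC_CLASSES) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9)
    stop("func_class_probs must be non-negative, named by functional ",
         "class, and sum to 1")
  if (cfg$strand_flip_prob < 0 || cfg$strand_flip_prob > 1)
    stop("strand_flip_prob must lie in [0, 1]")
  cfg
}

case_seed <- function(seed, case_index) {
  as.integer((as.numeric(seed) * 7919 + case_index * 104729) %% 2147483647)
}

rlogunif_int <- function(n, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  if (lo == hi) return(rep(as.integer(lo), n))
  pmin(as.integer(floor(exp(runif(n, log(lo), log(hi + 1))))), as.integer(hi))
}

# draw 96-context cells for n mutations of one category
draw_contexts <- function(n, mix, catalog) {
  if (n == 0L) return(integer(0))
  sig_idx <- sample(match(names(mix), colnames(catalog)), n, replace = TRUE,
                    prob = mix)
  vapply(sig_idx, function(j)
    sample.int(96L, 1L, prob = catalog[, j]), 1L)
}

#' Simulate one case's paired callset
#'
#' Draws trunk and branch sizes, contexts, true allele frequencies, depths
#' and detection as described in [sim_config()]. Trunk mutations undergo
#' detection independently in each lesion, so a trunk mutation dropped in
#' one lesion appears lesion-specific in the observed callset; branch
#' mutations only ever exist in their own lesion.
#'
#' @param config a [sim_config()].
#' @param case_id case label.
#' @param case_index integer used (with `config$seed`) to seed this case's
#'   RNG stream.
#' @return list with `pair` (a [paired_callset()]) and `truth` (a
#'   `data.table`: one row per simulated mutation with its true category,
#'   true VAF and per-lesion detection flags).
#' @export
simulate_case <- function(config, case_id, case_index = 1L) {
  config <- validate_sim_config(config)
  set.seed(case_seed(config$seed, case_index))

  n_trunk <- rlogunif_int(1L, config$trunk_bounds)
  n_bp <- rlogunif_int(1L, config$branch_bounds_primary)
  n_bc <- rlogunif_int(1L, config$branch_bounds_ctc)
  n_all <- n_trunk + n_bp + n_bc
  category <- rep(c("trunk", "primary_branch", "ctc_branch"),
                  c(n_trunk, n_bp, n_bc))
  mix_of <- c(trunk = "common", primary_branch = "primary_specific",
              ctc_branch = "ctc_specific")

  # functional class first: indels carry no context
  fclass <- sample(names(config$func_class_probs), n_all, replace = TRUE,
                   prob = config$func_class_probs)
  is_indel <- fclass == "indel"

  labels <- context_labels_96()
  ctx_cell <- integer(n_all)
  for (cat_ in SIM_CATEGORIES) {
    sel <- which(mix_of[category] == cat_ & !is_indel)
    ctx_cell[sel] <- draw_contexts(length(sel),
                                   config$signature_mix[[cat_]],
                                   config$catalog)
  }
  lab <- ifelse(is_indel, NA_character_, labels[pmax(ctx_cell, 1L)])
  cls <- sub(".*\\[(.*)\\].*", "\\1", lab)
  ref <- substr(cls, 1L, 1L)
  alt <- substr(cls, 3L, 3L)
  context <- paste0(substr(lab, 1L, 1L), ref, substr(lab, 7L, 7L))

  # report some SNVs on the purine strand
  flip <- !is_indel & runif(n_all) < config$strand_flip_prob
  if (any(flip)) {
    ref[flip] <- chartr("CT", "GA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    context[flip] <- revcomp(context[flip])
  }

  # indel alleles: 1-base reference, insertion or deletion of 1-3 bases
  if (any(is_indel)) {
    k <- sum(is_indel)
    anchor <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    ins <- runif(k) < 0.5
    tail_len <- sample.int(3L, k, replace = TRUE)
    tails <- vapply(tail_len, function(m)
      paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
            collapse = ""), "")
    ref[is_indel] <- ifelse(ins, anchor, paste0(anchor, tails))
    alt[is_indel] <- ifelse(ins, paste0(anchor, tails), anchor)
    context[is_indel] <- NA_character_
  }

  pos <- sample.int(2^28, n_all, replace = FALSE)
  truth <- data.table(
    case_id = case_id, chrom = "SIM1", pos = pos, ref = ref, alt = alt,
    gene = sample(config$gene_pool, n_all, replace = TRUE),
    func_class = fclass, context = context, category = category)
  truth[, true_vaf := {
    v <- numeric(.N)
    for (cat_ in SIM_CATEGORIES) {
      sel <- mix_of[category] == cat_
      ab <- config$vaf_beta[[cat_]]
      v[sel] <- rbeta(sum(sel), ab[1], ab[2])
    }
    v
  }]

  detect <- function(active) {
    depth <- rpois(n_all, config$depth_mean)
    alt_reads <- rbinom(n_all, depth, truth$true_vaf)
    hit <- active & alt_reads >= config$min_alt_reads &
      runif(n_all) < config$detect_prob
    list(hit = hit, alt = alt_reads, refr = depth - alt_reads)
  }
  in_primary <- category %in% c("trunk", "primary_branch")
  in_ctc <- category %in% c("trunk", "ctc_branch")
  dp <- detect(in_primary)
  dc <- detect(in_ctc)
  truth[, detected_primary := dp$hit]
  truth[, detected_ctc := dc$hit]

  mk_records <- function(d) {
    idx <- which(d$hit)
    data.table(case_id = case_id, lesion = NA_character_,
               chrom = "SIM1", pos = truth$pos[idx], ref = truth$ref[idx],
               alt = truth$alt[idx], gene = truth$gene[idx],
               func_class = truth$func_class[idx],
               context = truth$context[idx],
               alt_depth = d$alt[idx], ref_depth = d$refr[idx])
  }
  pair <- paired_callset(case_id, mk_records(dp), mk_records(dc))
  list(pair = pair, truth = truth[])
}

#' Simulate a cohort of paired callsets
#'
#' @param config a [sim_config()].
#' @param case_prefix prefix of generated case labels.
#' @return list with `pairs` (list of [paired_callset()]), `truth` (row-bound
#'   truth table for all cases) and `metadata` (a cohort-metadata stub whose
#'   phenotype counts are internally consistent).
#' @export
simulate_cohort <- function(config, case_prefix = "SIM") {
  config <- validate_sim_config(config)
  ids <- sprintf("%s%02d", case_prefix, seq_len(config$n_cases))
  sims <- lapply(seq_len(config$n_cases), function(i)
    simulate_case(config, ids[i], i))
  truth <- rbindlist(lapply(sims, `[[`, "truth"))
  set.seed(case_seed(config$seed, 0L))
  stages <- sample(c("Ta", "T1", "T2a", "T2b", "T3a", "T4a"),
                   config$n_cases, replace = TRUE,
                   prob = c(3, 4, 2, 2, 7, 2) / 20)
  ph <- matrix(rpois(3L * config$n_cases, 5), ncol = 3L)
  metadata <- data.table(
    case_id = ids, t_stage = stages,
    lvi = runif(config$n_cases) < 0.4,
    vein_invasion = runif(config$n_cases) < 0.3,
    vim_pos_ck_neg = ph[, 1L], vim_neg_ck_pos = ph[, 2L],
    vim_pos_ck_pos = ph[, 3L], total_ctc = rowSums(ph))
  list(pairs = lapply(sims, `[[`, "pair"), truth = truth,
       metadata = metadata)
}

#' Closed-form expected concordance under trunk-branch detection
#'
#' With `T` trunk mutations, `Bp`/`Bc` private branch mutations and overall
#' per-mutation detection probabilities `dp`, `dc` in the two lesions, the
#' expected fraction of observed mutations seen in both lesions is
#' \deqn{\frac{T d_p d_c}{T (1 - (1-d_p)(1-d_c)) + B_p d_p + B_c d_c}.}
#'
#' @param trunk,branch_p,branch_c non-negative expected counts, not all 0.
#' @param dp,dc overall detection probabilities in `[0, 1]`.
#' @return expected concordance fraction.
#' @export
expected_concordance <- function(trunk, branch_p, branch_c, dp = 1, dc = 1) {
  if (any(c(trunk, branch_p, branch_c) < 0) ||
      all(c(trunk, branch_p, branch_c) == 0))
    stop("counts must be non-negative and not all zero")
  if (any(c(dp, dc) < 0) || any(c(dp, dc) > 1))
    stop("detection probabilities must lie in [0, 1]")
  denom <- trunk * (1 - (1 - dp) * (1 - dc)) + branch_p * dp + branch_c * dc
  if (denom == 0)
    stop("expected observed union is empty; concordance undefined")
  trunk * dp * dc / denom
}

#' Read a simulator configuration from a flat key-value file
#'
#' YAML-compatible `key: value` lines for the scalar simulator parameters
#' (`n_cases`, `trunk_min`, `trunk_max`, `branch_primary_min`,
#' `branch_primary_max`, `branch_ctc_min`, `branch_ctc_max`, `depth_mean`,
#' `min_alt_reads`, `detect_prob`, `strand_flip_prob`, `seed`). Blank lines
#' and `#` comments are ignored; unknown keys are an error. Structured
#' parameters (signature mixes, Beta parameters, catalog) keep their
#' defaults and are set programmatically via [sim_config()].
#'
#' @param path config file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("config lines must be 'key: value' pairs")
  vals <- setNames(as.numeric(trimws(vapply(kv, `[`, "", 2L))),
                   trimws(vapply(kv, `[`, "", 1L)))
  if (anyNA(vals)) stop("non-numeric config value")
  known <- c("n_cases", "trunk_min", "trunk_max", "branch_primary_min",
             "branch_primary_max", "branch_ctc_min", "branch_ctc_max",
             "depth_mean", "min_alt_reads", "detect_prob",
             "strand_flip_prob", "seed")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  pick <- function(k, d) if (k %in% names(vals)) unname(vals[k]) else d
  sim_config(
    n_cases = as.integer(pick("n_cases", 20)),
    trunk_bounds = c(pick("trunk_min", 10), pick("trunk_max", 150)),
    branch_bounds_primary = c(pick("branch_primary_min", 20),
                              pick("branch_primary_max", 1400)),
    branch_bounds_ctc = c(pick("branch_ctc_min", 20),
                          pick("branch_ctc_max", 1400)),
    depth_mean = pick("depth_mean", 100),
    min_alt_reads = as.integer(pick("min_alt_reads", 3)),
    detect_prob = pick("detect_prob", 1),
    strand_flip_prob = pick("strand_flip_prob", 0.5),
    seed = as.integer(pick("seed", 1)))
}

#' Overall detection probability implied by a simulator configuration
#'
#' Folds the binomial alternate-read threshold into a single per-mutation
#' detection probability: with depth `~ Poisson(depth_mean)` and VAF
#' `~ Beta(alpha, beta)`, alternate reads are Poisson with mean
#' `depth_mean * vaf`, so the detection probability is
#' `detect_prob * E_v[P(Pois(depth_mean v) >= min_alt_reads)]`, evaluated
#' by numerical integration over the Beta density.
#'
#' @param vaf_beta `c(alpha, beta)` of the true-VAF distribution.
#' @param depth_mean mean Poisson depth.
#' @param min_alt_reads detection threshold.
#' @param detect_prob extra Bernoulli sensitivity.
#' @return probability in `[0, 1]`.
#' @export
detection_probability <- function(vaf_beta, depth_mean, min_alt_reads,
                                  detect_prob = 1) {
  if (min_alt_reads <= 0) return(detect_prob)
  f <- function(v)
    dbeta(v, vaf_beta[1], vaf_beta[2]) *
      ppois(min_alt_reads - 1, depth_mean * v, lower.tail = FALSE)
  detect_prob * integrate(f, 0, 1, rel.tol = 1e-9)$value
}
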