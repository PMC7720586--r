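# End-to-end orchestration: simulate and/or analyze, then write a
# deterministic TSV report bundle with a machine-readable manifest.

#' Build a pipeline run configuration
#'
#' Exactly one input source is allowed: either file inputs (`callset_path`,
#' a MAF-like TSV holding every case's two lesions) for `mode = "analyze"`,
#' or a [sim_config()] for `mode = "simulate"` / `mode = "full"`.
#'
#' @param mode `"simulate"` (write callsets + truth), `"analyze"` (read
#'   callsets, write analysis tables) or `"full"` (both, in memory).
#' @param out_dir output directory (created; must be empty or absent).
#' @param seed integer seed recorded in every output header; overrides the
#'   seed inside `simulation` when given.
#' @param simulation a [sim_config()], for simulate/full modes.
#' @param callset_path MAF-like TSV of observed callsets, for analyze mode.
#' @param catalog_path signature catalog TSV (default: packaged toy
#'   catalog).
#' @param gene_list_path cancer-gene list (default: packaged list).
#' @param metadata_path optional cohort metadata TSV.
#' @param min_cases gene-recurrence threshold.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       out_dir,
                       seed = 1L,
                       simulation = NULL,
                       callset_path = NULL,
                       catalog_path = NULL,
                       gene_list_path = NULL,
                       metadata_path = NULL,
                       min_cases = 3L) {
  mode <- match.arg(mode)
  has_files <- !is.null(callset_path)
  has_sim <- !is.null(simulation)
  if (mode %in% c("simulate", "full")) {
    if (has_files)
      stop("mode '", mode, "' takes a simulation config, not input files")
    if (!has_sim) simulation <- sim_config(seed = seed)
    simulation$seed <- as.integer(seed)
    simulation <- validate_sim_config(simulation)
  } else {
    if (!has_files || has_sim)
      stop("mode 'analyze' takes callset_path (and no simulation config)")
  }
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation, callset_path = callset_path,
                 catalog_path = catalog_path,
                 gene_list_path = gene_list_path,
                 metadata_path = metadata_path,
                 min_cases = as.integer(min_cases)),
            class = "run_config")
}

split_into_pairs <- function(records) {
  records <- validate_mutations(records)
  lapply(split(records, by = "case_id", sorted = TRUE), function(dt)
    paired_callset(dt$case_id[1L], dt[lesion == "primary"],
                   dt[lesion == "ctc"]))
}

write_report_table <- function(dt, path, header_line) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_line, con)
  lines <- capture.output(fwrite(dt, sep = "\t", na = "NA", quote = FALSE))
  writeLines(lines, con)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> classify -> summarize and writes a report
#' bundle of plain TSV tables, each carrying one commented header line with
#' the manifest hash and seed: abundance/concordance per case, regional
#' proportions, consequence and NS/S tables, 6- and 96-class spectra per
#' category, signature exposures with a Newick dendrogram, VAF clonality
#' summaries and tests, gene recurrence, the optional cohort-metadata
#' summary, and `manifest.json`. Identical configuration and seed give a
#' byte-identical bundle.
#'
#' @param rc a [run_config()].
#' @return (invisibly) list with the in-memory tables and the manifest.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(fmt, ...)
    message(sprintf("[ctcmut %6.2fs] ", proc.time()[["elapsed"]] - t0),
            sprintf(fmt, ...))

  catalog_path <- rc$catalog_path %||%
    system.file("extdata", "toy_signatures.tsv", package = "ctcmut")
  gene_path <- rc$gene_list_path %||%
    system.file("extdata", "cancer_genes.txt", package = "ctcmut")
  catalog <- read_signature_catalog(catalog_path)
  gene_list <- read_gene_list(gene_path)

  # ---- inputs ----
  truth <- NULL
  if (rc$mode %in% c("simulate", "full")) {
    log_stage("simulating %d cases (seed %d)", rc$simulation$n_cases,
              rc$seed)
    sim <- simulate_cohort(rc$simulation)
    pairs <- sim$pairs
    truth <- sim$truth
    metadata <- sim$metadata
  } else {
    log_stage("reading callsets from %s", rc$callset_path)
    pairs <- split_into_pairs(read_maf_table(rc$callset_path))
    metadata <- if (!is.null(rc$metadata_path))
      read_cohort_metadata(rc$metadata_path) else NULL
  }
  if (!is.null(rc$metadata_path) && rc$mode != "analyze")
    metadata <- read_cohort_metadata(rc$metadata_path)

  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- manifest (hashed before tables are written) ----
  manifest <- list(
    package = "ctcmut",
    version = as.character(utils::packageVersion("ctcmut")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = rc$mode, seed = rc$seed,
    n_cases = length(pairs),
    inputs = list(callset_path = rc$callset_path,
                  catalog_path = catalog_path,
                  gene_list_path = gene_path,
                  metadata_path = rc$metadata_path),
    simulation = if (!is.null(rc$simulation))
      rc$simulation[c("n_cases", "trunk_bounds", "branch_bounds_primary",
                      "branch_bounds_ctc", "depth_mean", "min_alt_reads",
                      "detect_prob", "strand_flip_prob", "seed")])
  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                    null = "null", digits = NA)
  tmp <- tempfile(); writeLines(manifest_json, tmp)
  manifest_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  hdr <- sprintf("# ctcmut manifest=%s seed=%d", manifest_hash, rc$seed)
  emit <- function(dt, name)
    write_report_table(dt, file.path(rc$out_dir, name), hdr)

  out <- list(manifest = manifest)

  if (rc$mode == "simulate") {
    log_stage("writing simulated callsets and truth")
    all_rec <- rbindlist(lapply(pairs, function(p)
      rbind(p$primary, p$ctc)))
    emit(all_rec, "callsets.tsv")
    emit(truth, "truth.tsv")
    emit(metadata, "cohort_metadata.tsv")
    writeLines(manifest_json, file.path(rc$out_dir, "manifest.json"))
    log_stage("done")
    return(invisible(out))
  }

  # ---- analysis ----
  log_stage("classifying %d cases", length(pairs))
  classified <- rbindlist(lapply(pairs, annotate_categories))
  conc <- cohort_concordance_table(pairs)
  emit(conc, "concordance.tsv")

  abun <- tryCatch(abundance_correlation(pairs), error = function(e) NULL)
  abund_tab <- data.table(
    case_id = conc$case_id, n_primary = conc$n_primary,
    n_ctc = conc$n_ctc)
  emit(abund_tab, "abundance.tsv")
  corr_tab <- if (is.null(abun))
    data.table(statistic = c("pearson_r", "p_value", "n"),
               value = NA_real_) else
    data.table(statistic = c("pearson_r", "p_value", "n"),
               value = c(abun$r, abun$p_value, abun$n))
  emit(corr_tab, "abundance_correlation.tsv")

  reg <- conc[, .(case_id,
                  prop_common = n_common /
                    (n_common + n_primary_specific + n_ctc_specific),
                  prop_primary_specific = n_primary_specific /
                    (n_common + n_primary_specific + n_ctc_specific),
                  prop_ctc_specific = n_ctc_specific /
                    (n_common + n_primary_specific + n_ctc_specific))]
  emit(reg, "regional_proportions.tsv")

  log_stage("consequences and spectra")
  cons <- consequence_table(classified)
  cons_tab <- copy(cons$proportions)
  cons_tab[, ns_s_ratio := cons$ns_s[category]]
  emit(cons_tab, "consequence.tsv")

  uniq <- unique(classified, by = c("case_id", "key", "category"))
  spec6 <- rbindlist(lapply(split(uniq, by = "category", sorted = TRUE),
    function(dt) {
      sp <- mutation_spectrum(dt, 6L)
      data.table(category = dt$category[1L], klass = names(sp$counts),
                 count = as.numeric(sp$counts))
    }))
  emit(dcast(spec6, category ~ klass, value.var = "count"),
       "spectrum6.tsv")
  spec96_list <- lapply(split(uniq, by = "category", sorted = TRUE),
                        function(dt) mutation_spectrum(dt, 96L))
  spec96 <- rbindlist(lapply(names(spec96_list), function(nm)
    data.table(category = nm, context = names(spec96_list[[nm]]$counts),
               count = as.numeric(spec96_list[[nm]]$counts))))
  emit(dcast(spec96, category ~ context, value.var = "count"),
       "spectrum96.tsv")

  log_stage("refitting signature exposures")
  fits <- lapply(spec96_list, function(sp)
    if (!sp$empty) refit_exposures(sp, catalog) else NULL)
  keep <- !vapply(fits, is.null, TRUE)
  expo_tab <- rbindlist(lapply(names(fits)[keep], function(nm) {
    f <- fits[[nm]]
    data.table(profile = nm, t(f$exposures),
               residual = f$residual, cosine = f$cosine,
               low_confidence = f$low_confidence)
  }))
  if (!nrow(expo_tab))
    expo_tab <- setNames(
      data.table(character(), t(numeric(ncol(catalog)))[0, , drop = FALSE],
                 numeric(), numeric(), logical()),
      c("profile", colnames(catalog), "residual", "cosine",
        "low_confidence"))
  emit(expo_tab, "exposures.tsv")
  if (sum(keep) >= 2L) {
    emat <- do.call(rbind, lapply(fits[keep], `[[`, "exposures"))
    rownames(emat) <- names(fits)[keep]
    cl <- cluster_exposures(emat)
    writeLines(c(hdr, cl$newick), file.path(rc$out_dir, "exposures.nwk"))
  }

  log_stage("VAF clonality and gene recurrence")
  vafres <- compare_vaf_by_category(classified)
  emit(vafres$summary, "vaf_summary.tsv")
  emit(vafres$tests, "vaf_tests.tsv")
  genes <- recurrent_gene_table(classified, gene_list, rc$min_cases)
  emit(genes, "gene_recurrence.tsv")

  if (!is.null(metadata)) {
    ms <- summarize_cohort_metadata(metadata)
    meta_tab <- data.table(statistic = c("n_cases",
                                         paste0("stage_",
                                                names(ms$stage_counts)),
                                         "n_inconsistent"),
                           value = c(ms$n_cases,
                                     as.numeric(ms$stage_counts),
                                     ms$n_inconsistent))
    emit(meta_tab, "cohort_metadata_summary.tsv")
  }

  if (rc$mode == "full") {
    all_rec <- rbindlist(lapply(pairs, function(p)
      rbind(p$primary, p$ctc)))
    emit(all_rec, "callsets.tsv")
    emit(truth, "truth.tsv")
  }
  writeLines(manifest_json, file.path(rc$out_dir, "manifest.json"))
  log_stage("done: %d tables in %s",
            length(list.files(rc$out_dir)), rc$out_dir)

  out$concordance <- conc
  out$abundance_correlation <- abun
  out$consequence <- cons
  out$exposures <- fits
  out$vaf <- vafres
  out$genes <- genes
  out$pairs <- pairs
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
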