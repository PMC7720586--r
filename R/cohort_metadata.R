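# Clinical cohort metadata: pathologic stage, invasion flags, and
# immunophenotype CTC enumeration (Vim+/CK-, Vim-/CK+, Vim+/CK+ counts from
# a fixed 5 ml blood draw).

METADATA_COLUMNS <- c("case_id", "t_stage", "lvi", "vein_invasion",
                      "vim_pos_ck_neg", "vim_neg_ck_pos", "vim_pos_ck_pos",
                      "total_ctc")

#' Read a cohort metadata table
#'
#' TSV with header `case_id, t_stage, lvi, vein_invasion, vim_pos_ck_neg,
#' vim_neg_ck_pos, vim_pos_ck_pos, total_ctc`. Invasion flags are parsed as
#' logicals from `Pos`/`Neg` (case-insensitive; `TRUE`/`FALSE`, `1`/`0`
#' also accepted).
#'
#' @param path TSV path. The packaged transcription of a 20-patient bladder
#'   cancer cohort ships at
#'   `system.file("extdata", "cohort_table1.tsv", package = "ctcmut")`.
#' @return a `data.table`, one row per case.
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  miss <- setdiff(METADATA_COLUMNS, names(dt))
  if (length(miss))
    stop("metadata header missing columns: ", paste(miss, collapse = ", "))
  parse_flag <- function(x) {
    if (is.logical(x)) return(x)
    x <- tolower(as.character(x))
    out <- rep(NA, length(x))
    out[x %in% c("pos", "true", "1", "yes")] <- TRUE
    out[x %in% c("neg", "false", "0", "no")] <- FALSE
    out
  }
  dt[, lvi := parse_flag(lvi)]
  dt[, vein_invasion := parse_flag(vein_invasion)]
  for (col in c("vim_pos_ck_neg", "vim_neg_ck_pos", "vim_pos_ck_pos",
                "total_ctc"))
    dt[, (col) := as.integer(get(col))]
  dt[]
}

#' Collapse a pathologic T sub-stage to its major stage
#'
#' `T3a -> T3`, `T2b -> T2`, `Ta`/`Tis` stay as written.
#'
#' @param t_stage character vector of stage strings.
#' @return character vector of major stages.
#' @export
major_t_stage <- function(t_stage) {
  m <- regexpr("^T(is|a|[0-9]+)", t_stage, ignore.case = TRUE)
  out <- rep(NA_character_, length(t_stage))
  hit <- m > 0L
  out[hit] <- regmatches(t_stage, m)
  # numeric stages upper-case; Ta / Tis keep their lower-case suffix
  ifelse(grepl("^T[0-9]+$", out, ignore.case = TRUE), toupper(out), out)
}

#' Summarize a cohort metadata table
#'
#' Counts cases per major T stage (sub-stages such as `T3a` grouped under
#' `T3`) and checks, per case, that the three immunophenotype counts sum to
#' the printed total CTC count. Inconsistent rows are reported, never
#' fatal.
#'
#' @param metadata table from [read_cohort_metadata()].
#' @return a list with `n_cases`, `stage_counts` (named integer vector),
#'   and `consistency` (a `data.table` with per-case `phenotype_sum`,
#'   `total_ctc` and a `consistent` flag).
#' @export
summarize_cohort_metadata <- function(metadata) {
  metadata <- as.data.table(metadata)
  cons <- metadata[, .(
    case_id,
    phenotype_sum = vim_pos_ck_neg + vim_neg_ck_pos + vim_pos_ck_pos,
    total_ctc)]
  cons[, consistent := phenotype_sum == total_ctc]
  st <- major_t_stage(metadata$t_stage)
  lev <- unique(c(intersect(c("Ta", "Tis", paste0("T", 1:4)), st),
                  sort(unique(st))))
  stage_counts <- table(factor(st, levels = lev))
  list(n_cases = nrow(metadata),
       stage_counts = c(stage_counts),
       consistency = cons[],
       n_inconsistent = sum(!cons$consistent, na.rm = TRUE))
}
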