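# Reading, validation and keying of mutation callsets.
#
# A mutation set is a data.table with one row per somatic call and columns
#   case_id, lesion, chrom, pos, ref, alt, gene, func_class, context,
#   alt_depth, ref_depth
# Optional fields are NA when absent. Coordinates are 1-based VCF-style and
# mutation identity is the exact tuple (chrom, pos, ref, alt); annotation
# never enters the key.

MAF_COLUMNS <- c("case_id", "lesion", "chrom", "pos", "ref", "alt",
                 "gene", "func_class", "context", "alt_depth", "ref_depth")
MAF_REQUIRED <- c("case_id", "lesion", "chrom", "pos", "ref", "alt")

FUNC_CLASSES <- c("missense", "nonsense", "silent", "splice", "indel", "other")
LESIONS <- c("primary", "ctc")

empty_mutation_set <- function() {
  data.table(case_id = character(), lesion = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(),
             func_class = character(), context = character(),
             alt_depth = integer(), ref_depth = integer())
}

#' Mutation identity keys
#'
#' Builds the `chrom:pos:ref:alt` identity string used to match mutations
#' across lesions. Gene symbols and annotation are deliberately excluded:
#' two calls are the same mutation iff their genomic tuple is identical.
#'
#' @param x a mutation set `data.table` (or anything with the four columns).
#' @return character vector of keys, one per row.
#' @export
mutation_keys <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Validate a mutation set
#'
#' Checks the row-level invariants of a mutation table: positive 1-based
#' positions, `ref != alt`, 3-mer contexts whose middle base equals the
#' reference for SNVs, `func_class == "indel"` exactly when allele lengths
#' differ, and non-negative depths.
#'
#' @param records mutation set `data.table`.
#' @param require_unique_keys if `TRUE`, fail when a (case, lesion) carries
#'   the same mutation key twice.
#' @return the validated `data.table`, invisibly.
#' @export
validate_mutations <- function(records, require_unique_keys = TRUE) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) return(invisible(empty_mutation_set()))
  miss <- setdiff(MAF_REQUIRED, names(records))
  if (length(miss))
    stop("mutation set is missing required columns: ",
         paste(miss, collapse = ", "))
  for (col in setdiff(MAF_COLUMNS, names(records)))
    records[, (col) := if (col %in% c("pos", "alt_depth", "ref_depth"))
      NA_integer_ else NA_character_]
  setcolorder(records, MAF_COLUMNS)

  if (anyNA(records$pos) || any(records$pos < 1L))
    stop("pos must be a positive 1-based integer for every record")
  if (any(!records$lesion %in% LESIONS))
    stop("lesion must be one of: ", paste(LESIONS, collapse = ", "))
  if (any(records$ref == records$alt))
    stop("ref and alt alleles must differ")
  bad_allele <- grepl("[^ACGT]", records$ref) | grepl("[^ACGT]", records$alt)
  if (any(bad_allele))
    stop("alleles must be non-empty strings over {A,C,G,T}; offending row ",
         which(bad_allele)[1L])

  fc <- records$func_class
  known <- is.na(fc) | fc %in% FUNC_CLASSES
  if (!all(known))
    stop("unknown func_class value(s): ",
         paste(unique(fc[!known]), collapse = ", "))
  is_indel_len <- nchar(records$ref) != nchar(records$alt)
  annotated <- !is.na(fc)
  mism <- annotated & ((fc == "indel") != is_indel_len)
  if (any(mism))
    stop("func_class 'indel' must coincide with differing allele lengths; ",
         "offending row ", which(mism)[1L])

  ctx <- records$context
  has_ctx <- !is.na(ctx) & nzchar(ctx)
  if (any(has_ctx)) {
    if (any(nchar(ctx[has_ctx]) != 3L) ||
        any(grepl("[^ACGT]", ctx[has_ctx])))
      stop("context must be a 3-mer over {A,C,G,T} when present")
    snv <- !is_indel_len
    mid <- substr(ctx, 2L, 2L)
    bad <- has_ctx & snv & mid != records$ref
    if (any(bad))
      stop("context middle base must equal ref for SNVs; offending row ",
           which(bad)[1L])
  }
  for (col in c("alt_depth", "ref_depth")) {
    v <- records[[col]]
    if (any(!is.na(v) & v < 0L)) stop(col, " must be non-negative")
  }

  if (require_unique_keys) {
    dup <- duplicated(records[, .(case_id, lesion, chrom, pos, ref, alt)])
    if (any(dup)) {
      i <- which(dup)[1L]
      stop("duplicate mutation key within a lesion: case ",
           records$case_id[i], " lesion ", records$lesion[i], " key ",
           mutation_keys(records[i]))
    }
  }
  invisible(records)
}

#' Read a MAF-like mutation table
#'
#' Reads a tab-separated callset with header columns `case_id, lesion,
#' chrom, pos, ref, alt` and optional `gene, func_class, context,
#' alt_depth, ref_depth`. Rows with unparseable integer fields raise an
#' error naming the offending line; duplicate (case, lesion, key) rows are
#' rejected.
#'
#' @param path path to the TSV file.
#' @param chrom_prefix `"asis"` (default) keeps chromosome labels verbatim,
#'   `"strip"` removes a leading `"chr"`, `"add"` prepends it.
#' @return a validated mutation set `data.table`.
#' @export
read_maf_table <- function(path, chrom_prefix = c("asis", "strip", "add")) {
  chrom_prefix <- match.arg(chrom_prefix)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = c("", "NA", "."))
  miss <- setdiff(MAF_REQUIRED, names(dt))
  if (length(miss))
    stop("MAF header must name columns ",
         paste(MAF_REQUIRED, collapse = ", "), "; missing: ",
         paste(miss, collapse = ", "))
  for (col in c("pos", "alt_depth", "ref_depth")) {
    if (!col %in% names(dt)) next
    raw <- dt[[col]]
    parsed <- suppressWarnings(as.integer(raw))
    bad <- !is.na(raw) & is.na(parsed)
    if (any(bad))
      stop("cannot parse '", raw[which(bad)[1L]], "' as integer ", col,
           " at line ", which(bad)[1L] + 1L, " of ", path)
    dt[, (col) := parsed]
  }
  dt <- normalize_chrom(dt, chrom_prefix)
  validate_mutations(dt)
}

normalize_chrom <- function(dt, chrom_prefix) {
  if (chrom_prefix == "strip") dt[, chrom := sub("^chr", "", chrom)]
  if (chrom_prefix == "add")
    dt[, chrom := ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))]
  dt
}

#' Write a mutation table to MAF-like TSV
#'
#' @param records mutation set `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf_table <- function(records, path) {
  records <- validate_mutations(records)
  fwrite(records, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' A case's paired callset
#'
#' Bundles the primary-lesion and CTC-lesion mutation sets of one case.
#' Within each lesion, mutation keys must be unique.
#'
#' @param case_id case identifier.
#' @param primary,ctc mutation set `data.table`s (the `case_id` and
#'   `lesion` columns are overwritten to match their slot).
#' @return an object of class `paired_callset`.
#' @export
paired_callset <- function(case_id, primary, ctc) {
  primary <- as.data.table(primary)
  ctc <- as.data.table(ctc)
  if (nrow(primary)) primary[, `:=`(case_id = case_id, lesion = "primary")]
  if (nrow(ctc)) ctc[, `:=`(case_id = case_id, lesion = "ctc")]
  primary <- validate_mutations(primary)
  ctc <- validate_mutations(ctc)
  structure(list(case_id = case_id, primary = primary, ctc = ctc),
            class = "paired_callset")
}

#' @export
print.paired_callset <- function(x, ...) {
  cat(sprintf("<paired_callset> case %s: %d primary, %d ctc mutations\n",
              x$case_id, nrow(x$primary), nrow(x$ctc)))
  invisible(x)
}

# ---- VCF -------------------------------------------------------------------

read_vcf_lesion <- function(path, case_id, lesion, chrom_prefix = "asis") {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)   # one row per alternate allele
  rr <- SummarizedExperiment::rowRanges(vcf)
  filt <- rr$FILTER
  keep <- filt %in% c("PASS", ".")
  n_dropped <- sum(!keep)

  info <- VariantAnnotation::info(vcf)
  geno <- VariantAnnotation::geno(vcf)
  grab_info <- function(nm) {
    if (nm %in% names(info)) as.character(info[[nm]]) else
      rep(NA_character_, length(rr))
  }
  alt_chr <- as.character(rr$ALT)
  dt <- data.table(
    case_id = case_id, lesion = lesion,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt_chr,
    gene = grab_info("GENE"),
    func_class = grab_info("FUNC"),
    context = grab_info("CTX"),
    alt_depth = NA_integer_, ref_depth = NA_integer_
  )
  if ("AD" %in% names(geno)) {
    ad <- geno$AD
    if (is.array(ad) && length(dim(ad)) == 3L) {
      # expand() turns Number=R into [variant, sample, ref/alt]
      dt[, ref_depth := as.integer(ad[, 1L, 1L])]
      dt[, alt_depth := as.integer(ad[, 1L, 2L])]
    } else if (is.matrix(ad) && is.list(ad[, 1L])) {
      adl <- ad[, 1L]
      safe_int <- function(v, i)
        if (length(v) >= i) as.integer(v[i]) else NA_integer_
      dt[, ref_depth := vapply(adl, safe_int, 1L, i = 1L)]
      dt[, alt_depth := vapply(adl, safe_int, 1L, i = 2L)]
    }
  }
  dt <- dt[keep]
  dt <- normalize_chrom(dt, chrom_prefix)
  dt <- validate_mutations(dt)
  attr(dt, "n_dropped_filter") <- n_dropped
  dt
}

#' Read a matched pair of single-sample VCF files
#'
#' Reads minimal VCF 4.x files (fixed columns plus FORMAT and one sample).
#' Multi-allelic records are split into one record per alternate allele.
#' Records whose FILTER is anything other than `PASS` or `.` are dropped and
#' counted in the attached load report. Allelic depths come from the `AD`
#' FORMAT field when present; gene symbol, functional class and
#' trinucleotide context come from the INFO keys `GENE`, `FUNC` and `CTX`
#' when declared in the header.
#'
#' @param primary_path,ctc_path VCF paths for the two lesions.
#' @param case_id case identifier applied to both callsets.
#' @param chrom_prefix see [read_maf_table()].
#' @return a [paired_callset()] with attribute `load_report`, a list with
#'   per-lesion dropped-record counts.
#' @export
read_vcf_pair <- function(primary_path, ctc_path, case_id,
                          chrom_prefix = "asis") {
  p <- read_vcf_lesion(primary_path, case_id, "primary", chrom_prefix)
  c_ <- read_vcf_lesion(ctc_path, case_id, "ctc", chrom_prefix)
  pair <- paired_callset(case_id, p, c_)
  attr(pair, "load_report") <- list(
    primary_dropped_filter = attr(p, "n_dropped_filter"),
    ctc_dropped_filter = attr(c_, "n_dropped_filter"))
  pair
}

#' Write one lesion's mutations as a minimal single-sample VCF
#'
#' Emits a VCF 4.2 file with INFO keys `GENE`, `FUNC`, `CTX` and an `AD`
#' FORMAT field, the dialect [read_vcf_pair()] reads back.
#'
#' @param records mutation set rows of a single (case, lesion).
#' @param path output path (conventionally `.vcf`).
#' @param sample_name sample column header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "SAMPLE") {
  records <- validate_mutations(records)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Trinucleotide context\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  info <- function(k, v) ifelse(is.na(v) | !nzchar(v), NA, paste0(k, "=", v))
  parts <- cbind(info("GENE", records$gene),
                 info("FUNC", records$func_class),
                 info("CTX", records$context))
  info_col <- apply(parts, 1L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) "." else paste(r, collapse = ";")
  })
  has_ad <- !is.na(records$alt_depth) & !is.na(records$ref_depth)
  fmt <- ifelse(has_ad, "AD", ".")
  smp <- ifelse(has_ad, paste(records$ref_depth, records$alt_depth, sep = ","),
                ".")
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", info_col, fmt, smp, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- strand collapse and spectrum labels -----------------------------------

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), ""))
}

#' Collapse an SNV onto the pyrimidine strand
#'
#' Maps any of the 12 ordered single-base substitutions onto the six
#' pyrimidine-referenced classes `C>A, C>G, C>T, T>A, T>C, T>G`. When the
#' reference base is a purine the substitution and its trinucleotide
#' context are reverse-complemented, so the returned context always has a
#' pyrimidine middle base.
#'
#' @param ref,alt single-base allele vectors.
#' @param context optional 3-mer context vector (middle base must equal
#'   `ref`); `NA` entries pass through as `NA`.
#' @return a `data.table` with columns `class` and `context`.
#' @export
collapse_strand <- function(ref, alt, context = NULL) {
  n <- length(ref)
  if (length(alt) != n) stop("ref and alt must have equal length")
  if (is.null(context)) context <- rep(NA_character_, n)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("collapse_strand applies to single-base substitutions only")
  if (any(grepl("[^ACGT]", ref)) || any(grepl("[^ACGT]", alt)))
    stop("alleles must be A, C, G or T")
  has_ctx <- !is.na(context)
  if (any(has_ctx)) {
    if (any(nchar(context[has_ctx]) != 3L) ||
        any(grepl("[^ACGT]", context[has_ctx])))
      stop("context must be a 3-mer over {A,C,G,T}")
    if (any(substr(context[has_ctx], 2L, 2L) != ref[has_ctx]))
      stop("context middle base must equal ref")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- ref %in% c("A", "G")
  out_ref <- ref; out_alt <- alt; out_ctx <- context
  if (any(purine)) {
    out_ref[purine] <- chartr("AG", "TC", ref[purine])
    out_alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
    flip_ctx <- purine & has_ctx
    out_ctx[flip_ctx] <- revcomp(context[flip_ctx])
  }
  data.table(class = paste0(out_ref, ">", out_alt), context = out_ctx)
}

#' The 96 trinucleotide context labels
#'
#' Labels in the `"A[C>A]A"` convention, ordered lexicographically by
#' (substitution class, 5' base, 3' base) -- the standard catalog order.
#'
#' @return character vector of length 96.
#' @export
context_labels_96 <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(SUBSTITUTION_CLASSES, function(cl)
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", cl, "]", p3))))))
}

context_label <- function(class, context) {
  paste0(substr(context, 1L, 1L), "[", class, "]", substr(context, 3L, 3L))
}

# ---- signature catalog and gene list ---------------------------------------

#' Read a signature catalog
#'
#' Reads a TSV whose first column holds 96 context labels (`"A[C>A]A"`
#' convention) and whose remaining columns are signatures. Each signature
#' must be a probability distribution over the 96 contexts.
#'
#' @param path catalog TSV path.
#' @return a 96 x k numeric matrix, rows ordered as [context_labels_96()],
#'   columns named by signature.
#' @export
read_signature_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  labels <- as.character(dt[[1L]])
  mat <- as.matrix(dt[, -1L, with = FALSE])
  rownames(mat) <- labels
  validate_catalog(mat)
}

#' Validate a signature catalog matrix
#'
#' @param mat numeric matrix, 96 context rows x signature columns.
#' @return the matrix with rows reordered to the canonical context order.
#' @export
validate_catalog <- function(mat) {
  want <- context_labels_96()
  if (is.null(rownames(mat)) || !setequal(rownames(mat), want) ||
      nrow(mat) != 96L)
    stop("catalog must cover all 96 context labels exactly once")
  if (ncol(mat) < 1L) stop("catalog must contain at least one signature")
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop("catalog signatures must have unique names")
  mat <- mat[want, , drop = FALSE]
  if (any(mat < 0)) stop("catalog probabilities must be non-negative")
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-6))
    stop("each signature must sum to 1 within 1e-6; offending: ",
         paste(colnames(mat)[abs(sums - 1) > 1e-6], collapse = ", "))
  mat
}

#' Read a cancer-gene list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("gene list is empty: ", path)
  unique(x)
}
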