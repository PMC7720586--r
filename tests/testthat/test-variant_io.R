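test_that("MAF round-trip preserves the record multiset", {
  recs <- mk_records("C1", "primary", c(100, 200),
                     ref = c("C", "G"), alt = c("T", "A"),
                     gene = c("TP53", NA), func_class = c("missense", NA),
                     context = c("ACA", "TGC"),
                     alt_depth = c(8L, NA), ref_depth = c(12L, NA))
  path <- tempfile(fileext = ".tsv")
  write_maf_table(recs, path)
  back <- read_maf_table(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))

  # larger randomized round-trip
  set.seed(42)
  big <- rbind(random_mutation_set(80, "C1", "primary", with_depths = TRUE),
               random_mutation_set(60, "C1", "ctc", with_depths = TRUE))
  write_maf_table(big, path)
  again <- read_maf_table(path)
  expect_setequal(
    do.call(paste, as.data.frame(big)),
    do.call(paste, as.data.frame(again)))
})

test_that("MAF loader rejects malformed and duplicate rows", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("case_id\tlesion\tchrom\tpos\tref\talt",
               "C1\tprimary\t1\t100\tC\tT",
               "C1\tprimary\t1\tabc\tG\tA"), path)
  expect_error(read_maf_table(path), "line 3")

  writeLines(c("case_id\tlesion\tchrom\tpos\tref\talt",
               "C1\tprimary\t1\t100\tC\tT",
               "C1\tprimary\t1\t100\tC\tT"), path)
  expect_error(read_maf_table(path), "duplicate")

  writeLines(c("case_id\tchrom\tpos\tref\talt",
               "C1\t1\t100\tC\tT"), path)
  expect_error(read_maf_table(path), "lesion")
})

test_that("mutation-set invariants are enforced", {
  expect_error(validate_mutations(mk_records("C", "primary", 1, ref = "C",
                                             alt = "C")),
               "must differ")
  expect_error(validate_mutations(mk_records("C", "primary", 1,
                                             context = "AAA")),
               "middle base")
  # indel class must match allele-length difference, both directions
  expect_error(validate_mutations(
    mk_records("C", "primary", 1, ref = "C", alt = "CT",
               func_class = "missense")), "indel")
  expect_error(validate_mutations(
    mk_records("C", "primary", 1, func_class = "indel")), "indel")
  ok <- validate_mutations(mk_records("C", "primary", 1, ref = "C",
                                      alt = "CT", func_class = "indel"))
  expect_equal(nrow(ok), 1L)
})

test_that("VCF pair loading maps fields, splits ALTs and drops FILTER fails", {
  dir <- tempfile(); dir.create(dir)
  pvcf <- file.path(dir, "p.vcf"); cvcf <- file.path(dir, "c.vcf")
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"f\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"c\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  writeLines(c(hdr,
    "1\t100\t.\tC\tT\t.\tPASS\tGENE=TP53;FUNC=missense;CTX=ACA\tAD\t12,8",
    "1\t200\t.\tG\tA,T\t.\tPASS\t.\tAD\t20,5,3",
    "1\t300\t.\tC\tA\t.\tLowQual\t.\tAD\t9,9"), pvcf)
  writeLines(c(hdr,
    "1\t100\t.\tC\tT\t.\tPASS\tGENE=TP53;FUNC=missense;CTX=ACA\tAD\t30,10"),
    cvcf)
  pair <- read_vcf_pair(pvcf, cvcf, "K1")
  p <- pair$primary
  expect_equal(nrow(p), 3L)            # 1 SNV + 2 split alleles, 1 dropped
  expect_equal(attr(pair, "load_report")$primary_dropped_filter, 1L)
  one <- p[pos == 100]
  expect_equal(one$ref_depth, 12L)
  expect_equal(one$alt_depth, 8L)
  expect_equal(one$gene, "TP53")
  expect_equal(one$context, "ACA")
  split_alt <- p[pos == 200]
  expect_equal(nrow(split_alt), 2L)
  expect_setequal(split_alt$alt, c("A", "T"))
  expect_equal(unique(split_alt$ref), "G")
  expect_error(read_vcf_pair(file.path(dir, "absent.vcf"), cvcf, "K"),
               "no such file")
})

test_that("MAF and VCF loaders agree on key multisets", {
  set.seed(7)
  recs <- random_mutation_set(50, "C1", "primary", with_depths = TRUE)
  dir <- tempfile(); dir.create(dir)
  maf <- file.path(dir, "m.tsv"); vcfp <- file.path(dir, "p.vcf")
  write_maf_table(recs, maf)
  write_vcf(recs, vcfp)
  write_vcf(recs[1:2], file.path(dir, "c.vcf"))
  from_maf <- read_maf_table(maf)
  from_vcf <- read_vcf_pair(vcfp, file.path(dir, "c.vcf"), "C1")$primary
  expect_setequal(mutation_keys(from_maf), mutation_keys(from_vcf))
  expect_identical(sort(vaf(from_maf)), sort(vaf(from_vcf)))
})

test_that("collapse_strand maps all 12 substitutions onto 6 classes", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  out <- collapse_strand(pairs$ref, pairs$alt)
  # brute-force expectation: pyrimidine pass-through, purine complemented
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expected <- ifelse(pairs$ref %in% c("C", "T"),
                     paste0(pairs$ref, ">", pairs$alt),
                     paste0(comp[pairs$ref], ">", comp[pairs$alt]))
  expect_identical(out$class, unname(expected))
  expect_setequal(out$class, c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_true(all(table(out$class) == 2L))
})

test_that("collapse_strand handles contexts, is idempotent and strand-stable", {
  expect_identical(as.list(collapse_strand("C", "T", "ACA")),
                   list(class = "C>T", context = "ACA"))
  expect_identical(as.list(collapse_strand("G", "A", "AGT")),
                   list(class = "C>T", context = "ACT"))
  expect_error(collapse_strand("C", "N"), "A, C, G or T")

  set.seed(3)
  recs <- random_mutation_set(200)
  out <- collapse_strand(recs$ref, recs$alt, recs$context)
  # idempotence on its own (pyrimidine) output
  out_ref <- substr(out$class, 1, 1)
  out_alt <- substr(out$class, 3, 3)
  again <- collapse_strand(out_ref, out_alt, out$context)
  expect_identical(again, out)
  # reverse-complemented input collapses to the identical output
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- collapse_strand(rc[recs$ref], rc[recs$alt],
                             vapply(strsplit(recs$context, ""),
                                    function(ch) paste(rev(rc[ch]),
                                                       collapse = ""), ""))
  expect_identical(flipped, out)
})

test_that("signature catalog validation catches malformed catalogs", {
  cat_ <- toy_catalog()
  expect_equal(dim(cat_), c(96L, 5L))
  expect_true(all(abs(colSums(cat_) - 1) < 1e-6))
  bad <- cat_; bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(validate_catalog(bad), "sum to 1")
  expect_error(validate_catalog(cat_[1:95, ]), "96")
  neg <- cat_; neg[1, 1] <- -1e-3; neg[2, 1] <- neg[2, 1] + 1e-3
  expect_error(validate_catalog(neg), "non-negative")
})
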