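test_that("consequence table computes proportions and NS/S ratios", {
  recs <- dt_with_key(
    case_id = "A", key_col = as.character(1:11),
    category = c(rep("common", 8), rep("primary_specific", 3)),
    func_class = c(rep("missense", 6), rep("silent", 2),
                   rep("missense", 3)))
  out <- consequence_table(recs)
  expect_equal(unname(out$ns_s["common"]), 3.0)
  expect_true(is.na(out$ns_s["primary_specific"]))   # zero silent
  pc <- out$proportions[category == "common"]
  expect_equal(pc$missense, 0.75)
  expect_equal(pc$silent, 0.25)
  # numerator option
  recs2 <- rbind(recs,
                 dt_with_key(case_id = "A", key_col = "12",
                             category = "common",
                             func_class = "nonsense"))
  out2 <- consequence_table(recs2, ns_numerator = "missense+nonsense")
  expect_equal(unname(out2$ns_s["common"]), 3.5)
})

test_that("simulated consequence mix recovers the configured NS/S ratio", {
  cfg <- sim_config(n_cases = 1L, trunk_bounds = c(1000L, 1000L),
                    branch_bounds_primary = c(20L, 20L),
                    branch_bounds_ctc = c(20L, 20L),
                    func_class_probs = c(missense = 0.5, silent = 0.2,
                                         other = 0.3),
                    min_alt_reads = 0L, seed = 13L)
  sim <- simulate_case(cfg, "X", 1L)
  ann <- annotate_categories(sim$pair)
  out <- consequence_table(ann)
  n_sil <- 1000 * 0.2
  # 3 binomial standard errors around ratio 2.5 at n = 1000
  se_ratio <- 2.5 * sqrt(1 / (1000 * 0.5) + 1 / n_sil)
  expect_lt(abs(out$ns_s["common"] - 2.5), 3 * se_ratio)
})

test_that("spectra count what a per-record tally counts", {
  # single-class inputs collapse fully onto C>T
  recs <- rbind(mk_records("A", "primary", 1:3, ref = "C", alt = "T",
                           context = "ACA"),
                mk_records("A", "primary", 4:6, ref = "G", alt = "A",
                           context = "TGT"))
  sp <- mutation_spectrum(recs, 6L)
  expect_equal(unname(sp$counts["C>T"]), 6)
  expect_equal(sum(sp$counts), 6)

  empty <- mutation_spectrum(recs[0], 6L)
  expect_true(empty$empty)
  expect_equal(sum(empty$counts), 0)
  expect_error(mutation_spectrum(recs[0], 6L, normalize = TRUE),
               "all-zero")

  set.seed(17)
  mixed <- random_mutation_set(300)
  sp96 <- mutation_spectrum(mixed, 96L)
  # enumeration oracle: loop records, build label by hand
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- setNames(numeric(96), context_labels_96())
  for (i in seq_len(nrow(mixed))) {
    r <- mixed$ref[i]; a <- mixed$alt[i]; cx <- strsplit(mixed$context[i],
                                                         "")[[1]]
    if (r %in% c("A", "G")) {
      r2 <- comp[r]; a2 <- comp[a]; cx <- rev(comp[cx])
    } else { r2 <- r; a2 <- a }
    lab <- paste0(cx[1], "[", r2, ">", a2, "]", cx[3])
    oracle[lab] <- oracle[lab] + 1
  }
  expect_equal(sp96$counts, oracle)
  # 6-class view is the 96-class view marginalized
  sp6 <- mutation_spectrum(mixed, 6L)
  cls96 <- sub(".*\\[(.*)\\].*", "\\1", names(sp96$counts))
  expect_equal(sp6$counts, tapply(sp96$counts, cls96, sum)[names(sp6$counts)],
               ignore_attr = TRUE)
})

test_that("spectrum of a union is the sum of spectra (disjoint sets)", {
  set.seed(19)
  a <- random_mutation_set(100, "A")
  b <- random_mutation_set(80, "B")
  sa <- mutation_spectrum(a, 96L)$counts
  sb <- mutation_spectrum(b, 96L)$counts
  su <- mutation_spectrum(rbind(a, b), 96L)$counts
  expect_equal(su, sa + sb)
})

test_that("indels and missing contexts are skipped with a count", {
  recs <- rbind(mk_records("A", "primary", 1:4, ref = "C", alt = "T",
                           context = "ACA"),
                mk_records("A", "primary", 5, ref = "C", alt = "CT",
                           func_class = "indel"),
                mk_records("A", "primary", 6, ref = "C", alt = "A"))
  sp96 <- mutation_spectrum(recs, 96L)
  expect_equal(sp96$n_used, 4L)
  expect_equal(sp96$n_skipped, 2L)     # indel + missing context
  sp6 <- mutation_spectrum(recs, 6L)
  expect_equal(sp6$n_used, 5L)         # context not needed for 6 classes
  expect_equal(sp6$n_skipped, 1L)
})

test_that("noiseless single-source spectra refit to the generating signature", {
  cat_ <- toy_catalog()
  v <- 100 * cat_[, "APOBEC"]
  fit <- refit_exposures(v, cat_)
  expect_equal(unname(fit$exposures["APOBEC"]), 100, tolerance = 1e-8)
  expect_lt(sum(fit$exposures) - fit$exposures["APOBEC"],
            1e-6 * sum(fit$exposures))
  expect_equal(fit$cosine, 1, tolerance = 1e-9)
})

test_that("two-signature mixtures are recovered against a least-squares oracle", {
  cat_ <- toy_catalog()[, c("APOBEC", "CpG")]
  v <- 1000 * (0.7 * cat_[, "APOBEC"] + 0.3 * cat_[, "CpG"])
  fit <- refit_exposures(v, cat_)
  expect_equal(unname(fit$proportions), c(0.7, 0.3), tolerance = 1e-6)
  # oracle: unconstrained normal equations (interior solution, so equal)
  e_ls <- solve(crossprod(cat_), crossprod(cat_, v))
  expect_equal(unname(fit$exposures), unname(e_ls[, 1]), tolerance = 1e-6)
  expect_lt(fit$residual, 1e-8)
})

test_that("one-signature refit equals a grid-search projection", {
  set.seed(23)
  cat1 <- pure_ct_catalog()
  v <- runif(96) * 5 + 0.1
  names(v) <- context_labels_96()
  fit <- refit_exposures(v, cat1, low_confidence_below = 0)
  grid <- seq(0, 2 * sum(v), length.out = 200001)
  rss <- vapply(grid, function(g) sum((v - g * cat1[, 1])^2), 1)
  expect_equal(unname(fit$exposures[1]), grid[which.min(rss)],
               tolerance = 1e-4)
  # monotone improvement over the zero exposure
  expect_lte(fit$residual, sqrt(sum(v^2)))
})

test_that("refit residual never exceeds the zero-exposure residual", {
  set.seed(29)
  cat_ <- toy_catalog()
  for (i in 1:20) {
    v <- rpois(96, lambda = runif(1, 0.5, 10))
    names(v) <- context_labels_96()
    if (sum(v) == 0) next
    fit <- refit_exposures(v, cat_)
    expect_lte(fit$residual, sqrt(sum(v^2)) + 1e-9)
    expect_true(all(fit$exposures >= 0))
  }
  expect_error(refit_exposures(setNames(numeric(96), context_labels_96()),
                               cat_), "all-zero")
})

test_that("sparse spectra are flagged low-confidence", {
  cat_ <- toy_catalog()
  v <- 30 * cat_[, "FLAT"]
  expect_true(refit_exposures(v, cat_)$low_confidence)
  expect_false(refit_exposures(100 * cat_[, "FLAT"], cat_)$low_confidence)
})

test_that("exposure clustering matches a brute-force average-linkage oracle", {
  # identical pair merges first at height zero
  m <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 5))
  cl <- cluster_exposures(m)
  expect_equal(cl$hclust$height[1], 0)
  first_pair <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first_pair], c("a", "b"))

  # two profiles: single merge at their distance
  m2 <- rbind(p = c(1, 0), q = c(0, 1))
  cl2 <- cluster_exposures(m2, normalize = FALSE)
  expect_equal(cl2$hclust$height, sqrt(2))
  expect_match(cl2$newick, "^\\(")

  expect_error(cluster_exposures(m2[1, , drop = FALSE]), "at least 2")

  set.seed(37)
  for (i in 1:5) {
    m4 <- matrix(runif(24), nrow = 4,
                 dimnames = list(paste0("r", 1:4), NULL))
    cl4 <- cluster_exposures(m4, normalize = FALSE)
    expect_equal(sort(cl4$hclust$height),
                 sort(brute_average_linkage_heights(m4)),
                 tolerance = 1e-12)
    expect_true(all(diff(cl4$hclust$height) >= -1e-12))
  }
})
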