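test_that("perfect and anti-perfect predictions hit the metric extremes", {
  x <- c(0.2, 1.4, -0.5, 2.2, 0.9)
  m <- regression_metrics(x, x)
  expect_equal(m$r, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$slope, 1)
  expect_equal(regression_metrics(-x, x)$r, -1)
  expect_error(regression_metrics(rep(1, 5), x), "zero variance")
})

test_that("regression metrics match the textbook formulas on random vectors", {
  set.seed(42)
  p <- rnorm(50); e <- 0.6 * p + rnorm(50, 0, 0.5)
  m <- regression_metrics(p, e)
  r_hand <- sum((p - mean(p)) * (e - mean(e))) /
    sqrt(sum((p - mean(p))^2) * sum((e - mean(e))^2))
  expect_equal(m$r, r_hand, tolerance = 1e-10)
  expect_equal(m$rmse, sqrt(sum((p - e)^2) / 50), tolerance = 1e-10)
  expect_equal(m$slope,
               sum((p - mean(p)) * (e - mean(e))) / sum((p - mean(p))^2),
               tolerance = 1e-10)
})

test_that("perfect separation gives unit AUCs and unit max-MCC", {
  exp <- c(rep(2, 6), rep(0, 6))
  pred <- c(rep(1.5, 6), rep(-0.5, 6))
  cm <- classification_metrics(pred, exp)
  expect_equal(cm$auc_roc, 1)
  expect_equal(cm$auc_pr, 1)
  expect_equal(cm$max_mcc, 1)
  expect_error(classification_metrics(pred, rep(2, 12)), "both classes")
})

test_that("the MCC of a perfect confusion matrix is 1 and degenerate factors give 0", {
  expect_equal(priddg:::.mcc(5, 5, 0, 0), 1)
  expect_equal(priddg:::.mcc(0, 0, 5, 5), -1)
  expect_equal(priddg:::.mcc(5, 0, 5, 0), 0)
})

test_that("label-independent predictions give chance-level ROC AUC", {
  set.seed(99)
  n <- 4000
  exp <- c(rnorm(n / 2, 2), rnorm(n / 2, 0))
  pred <- rnorm(n)
  cm <- classification_metrics(pred, exp)
  expect_lt(abs(cm$auc_roc - 0.5), 0.05)
})

test_that("the threshold-sweep ROC AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  exp <- rnorm(80, 1, 1)
  pred <- 0.5 * exp + rnorm(80, 0, 0.8)
  cm <- classification_metrics(pred, exp)
  ref <- as.numeric(pROC::auc(pROC::roc(exp >= 1, pred, quiet = TRUE,
                                        direction = "<")))
  expect_equal(cm$auc_roc, ref, tolerance = 1e-10)
})

test_that("CV3 makes one fold per complex and partitions the mutations", {
  d <- make_synthetic_dataset(n_complexes = 10, muts_per_complex = 8,
                              noise_sd = 0.76, seed = 21)
  res <- cross_validate(d, "CV3")
  expect_equal(nrow(res$rounds), 10)
  expect_setequal(res$pooled$mutation, d$mutation)
  expect_equal(nrow(res$pooled), nrow(d))
  expect_false(any(duplicated(res$pooled$mutation)))
})

test_that("CV1/CV2 rounds use disjoint train/test splits of the stated sizes", {
  d <- make_synthetic_dataset(n_complexes = 12, muts_per_complex = 6,
                              noise_sd = 0.76, seed = 22)
  r1 <- cross_validate(d, "CV1", repeats = 5, seed = 3)
  expect_equal(nrow(r1$rounds), 5)
  expect_true(all(r1$rounds$n_test == nrow(d) - round(0.5 * nrow(d))))
  r2 <- cross_validate(d, "CV2", repeats = 5, seed = 3)
  expect_true(all(r2$rounds$n_test == nrow(d) - round(0.8 * nrow(d))))
  # deterministic given the seed
  r1b <- cross_validate(d, "CV1", repeats = 5, seed = 3)
  expect_equal(r1$rounds$r, r1b$rounds$r)
  expect_equal(r1$aggregate$r, mean(r1$rounds$r))
})

test_that("pooled CV3 correlation tracks the generative model's correlation", {
  d <- make_synthetic_dataset(n_complexes = 50, muts_per_complex = 5,
                              noise_sd = 0.76, seed = 23)
  gen_r <- cor(d$ddg_true, d$ddg_exp)
  res <- cross_validate(d, "CV3")
  expect_lt(abs(res$aggregate$r - gen_r), 0.1)
})

test_that("a complex holding nearly all mutations is a degenerate fold", {
  d <- make_synthetic_dataset(n_complexes = 2, muts_per_complex = 8,
                              noise_sd = 0.5, seed = 24)
  expect_error(cross_validate(d, "CV3"), "degenerate fold")
})

test_that("curation applies the documented filters in order", {
  raw <- data.frame(
    pdb_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P6", "P6", "P7", "P7"),
    chain = "A",
    position = c(10, 11, 12, 13, 14, 15, 15, 15, 16, 16),
    wt_aa = c("L", "K", "R", "T", "S", "Y", "Y", "Y", "W", "W"),
    mut_aa = "A",
    ddg_exp = c(1.2, 0.5, 2.0, 1.1, 0.3, 1.0, 1.4, 1.2, 2.0, 0.2),
    protein_length = c(150, 19, 200, 210, 220, 230, 230, 230, 240, 240),
    rna_length = c(20, 30, 4, 25, 26, 27, 27, 27, 28, 28),
    modified_interface = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                           FALSE, FALSE, FALSE),
    metal_site = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, FALSE),
    stringsAsFactors = FALSE)
  out <- curate_dataset(raw)
  expect_true(any(grepl("protein length", out$rejected$reason)))
  expect_true(any(grepl("RNA length", out$rejected$reason)))
  expect_true(any(grepl("interface", out$rejected$reason)))
  expect_true(any(grepl("metal", out$rejected$reason)))
  # P6: three measurements spanning < 1 kcal/mol -> one averaged record
  p6 <- out$curated[out$curated$pdb_id == "P6", ]
  expect_equal(nrow(p6), 1)
  expect_equal(p6$ddg_exp, mean(c(1.0, 1.4, 1.2)))
  # P7: spread 1.8 kcal/mol -> rejected as inconsistent
  expect_false("P7" %in% out$curated$pdb_id)
  expect_true(any(grepl("inconsistent", out$rejected$reason)))
})

test_that("the RNA similarity rule rejects low-identity pairs", {
  raw <- data.frame(
    pdb_id = c("P1", "P2"), chain = "A", position = c(5, 6),
    wt_aa = c("L", "K"), mut_aa = "A", ddg_exp = c(1, 2),
    rna_seq_structure = c("ACGUACGUAC", "ACGUACGUAC"),
    rna_seq_assay = c("ACGUACGUAC", "ACGAUGGAAC"),
    stringsAsFactors = FALSE)
  # oracle identity for the second pair via direct alignment count
  sim2 <- rna_identity("ACGUACGUAC", "ACGAUGGAAC")
  out <- curate_dataset(raw)
  expect_true("P1" %in% out$curated$pdb_id)
  if (sim2 < 0.8) {
    expect_false("P2" %in% out$curated$pdb_id)
    expect_true(any(grepl("similarity", out$rejected$reason)))
  }
  expect_equal(rna_identity("ACGU", "ACGU"), 1)
  expect_lt(rna_identity("AAAAAAAAAA", "CCCCCCCCCC"), 0.2)
})

test_that("the bundled synthetic training table has the documented shape", {
  f <- system.file("extdata", "s248_synthetic.tsv", package = "priddg")
  tab <- read_ddg_table(f)
  expect_equal(nrow(tab), 248)
  expect_equal(length(unique(tab$pdb_id)), 50)
  expect_equal(sum(tab$ddg_exp >= 1), 124)
})
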