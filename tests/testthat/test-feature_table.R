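test_that("TSV loading types columns, treats NA spellings as missing, and validates IDs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\texpr\tdN",
               "SPAC1\t1.5\t0.1",
               "SPAC2\tNA\t0.2",
               "SPAC3\tnot_a_number\t0.3"), path)
  tab <- load_feature_table(path, response_names = "dN")
  expect_s3_class(tab, "feature_table")
  expect_equal(dim(tab), c(3L, 1L))
  expect_equal(colnames(tab$responses), "dN")
  expect_equal(tab$data$expr, c(1.5, NA, NA))     # missing, never coerced to 0
  expect_equal(tab$responses$dN, c(0.1, 0.2, 0.3))

  writeLines(c("gene\texpr\tdN", "SPAC1\t1\t0.1", "SPAC1\t2\t0.2"), path)
  expect_error(load_feature_table(path, response_names = "dN"), "SPAC1")
  writeLines(c("gene\texpr", "SPAC1\t1"), path)
  expect_error(load_feature_table(path, response_names = "dN"), "dN")
})

test_that("write/load round-trip preserves values, groups and kinds exactly", {
  ds <- small_study(seed = 3, n = 60)
  tab <- ds$table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- load_feature_table(path, schema = table_schema(tab),
                             response_names = colnames(tab$responses))
  expect_identical(back$gene_ids, tab$gene_ids)
  expect_identical(back$group, tab$group)
  expect_identical(back$kind, tab$kind)
  expect_equal(back$data, tab$data, tolerance = 0)
  expect_equal(back$responses, tab$responses, tolerance = 0)
})

test_that("one-hot encoding expands levels and membership sets, keeping all levels", {
  tab <- feature_table(
    data.frame(chr = c("II", "I", "III"),
               slims = c("cytoplasm,organelle", "nucleus", ""),
               stringsAsFactors = FALSE),
    gene_ids = c("g1", "g2", "g3"),
    group = c(chr = "chromosome", slims = "GO_component"),
    kind = c(chr = "categorical", slims = "categorical"))
  enc <- one_hot_encode(tab)
  expect_equal(unname(unlist(enc$data[1, c("chr.I", "chr.II", "chr.III")])),
               c(0, 1, 0))
  expect_equal(unname(unlist(enc$data[1, c("slims.cytoplasm", "slims.nucleus",
                                           "slims.organelle")])),
               c(1, 0, 1))
  expect_equal(unname(unlist(enc$data[3, startsWith(colnames(enc$data), "slims")])),
               c(0, 0, 0))
  expect_true(all(enc$kind[startsWith(names(enc$kind), "chr.")] == "binary"))
  expect_true(all(enc$group[startsWith(names(enc$group), "chr.")] == "chromosome"))
  expect_false("chr" %in% colnames(enc$data))

  # a single-level column becomes one all-ones column (zero variance later)
  tab1 <- feature_table(data.frame(chr = c("I", "I")), c("a", "b"),
                        c(chr = "chromosome"), c(chr = "categorical"))
  enc1 <- one_hot_encode(tab1)
  expect_equal(enc1$data[["chr.I"]], c(1, 1))

  # collision with an existing variable errors
  tab2 <- feature_table(data.frame(chr = c("I", "II"), chr.I = c(0, 1)),
                        c("a", "b"),
                        c(chr = "chromosome", chr.I = "other"),
                        c(chr = "categorical", chr.I = "binary"))
  expect_error(one_hot_encode(tab2, "chr"), "collision")
})

test_that("amino-acid scaling normalizes rows to 1 and is idempotent", {
  counts <- rbind(c(5, 5, 0), c(2, 3, 5), c(1, 1, 1))
  tab <- feature_table(as.data.frame(counts) |>
                         stats::setNames(c("aa_a", "aa_b", "aa_c")),
                       c("g1", "g2", "g3"),
                       stats::setNames(rep("amino_acid_composition", 3),
                                       c("aa_a", "aa_b", "aa_c")),
                       stats::setNames(rep("continuous", 3),
                                       c("aa_a", "aa_b", "aa_c")))
  sc <- scale_aa_composition(tab)
  expect_equal(unname(unlist(sc$data[1, ])), c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(rowSums(as.matrix(sc)), stats::setNames(rep(1, 3), sc$gene_ids),
               tolerance = 1e-12)
  twice <- scale_aa_composition(sc)
  expect_equal(as.matrix(twice), as.matrix(sc), tolerance = 1e-12)

  tab$data[2, ] <- c(0, 0, 0)
  expect_error(scale_aa_composition(tab), "g2")
})

test_that("preprocessing standardizes on the fitting subset and drops constants", {
  tab <- feature_table(data.frame(a = c(1, 2, 3), b = c(7, 7, 7)),
                       c("g1", "g2", "g3"),
                       c(a = "other", b = "other"),
                       c(a = "continuous", b = "continuous"))
  pp <- preprocess(tab)
  expect_equal(pp$table$data$a, c(-1, 0, 1))   # sample sd of (1,2,3) is 1
  expect_identical(pp$state$dropped, "b")
  expect_false("b" %in% colnames(pp$table$data))

  # idempotence: re-fitting on standardized output changes nothing
  again <- preprocess(pp$table)
  expect_equal(as.matrix(again$table), as.matrix(pp$table), tolerance = 1e-10)

  expect_error(preprocess(tab, fit_on = "g1"), "at least 2")
})

test_that("training statistics are applied unchanged to held-out genes", {
  ds <- small_study(seed = 11, n = 80)
  tab <- impute_missing(one_hot_encode(scale_aa_composition(ds$table)), seed = 1)
  fit_on <- tab$gene_ids[1:50]
  pp <- preprocess(tab, fit_on = fit_on)
  X <- as.matrix(pp$table)
  tr <- X[fit_on, , drop = FALSE]
  expect_lt(max(abs(colMeans(tr))), 1e-10)
  expect_equal(unname(apply(tr, 2, sd)), rep(1, ncol(tr)), tolerance = 1e-10)
  # held-out rows use the training mean/sd, not their own
  ho <- setdiff(tab$gene_ids, fit_on)
  v <- colnames(X)[1]
  expect_equal(X[ho, v],
               (as.matrix(tab)[ho, v] - pp$state$means[[v]]) / pp$state$sds[[v]])
})

test_that("imputation fills only missing entries, deterministically, and tracks a linear signal", {
  set.seed(5)
  n <- 200
  x <- runif(n, 1, 3)
  y <- 2 * x
  y[sample(n, 25)] <- NA
  tab <- feature_table(data.frame(x = x, y = y),
                       sprintf("g%03d", 1:n),
                       c(x = "expression", y = "expression"),
                       c(x = "continuous", y = "continuous"))
  imp <- impute_missing(tab, seed = 1)
  miss <- is.na(y)
  expect_equal(imp$data$y[!miss], y[!miss])          # observed cells untouched
  expect_equal(imp$data$x, x)
  expect_lt(max(abs(imp$data$y[miss] - 2 * x[miss]) / (2 * x[miss])), 0.10)

  imp2 <- impute_missing(tab, seed = 1)
  expect_identical(imp$data, imp2$data)              # bit-identical under a seed

  # a table with no missing entries passes through unchanged
  full <- tiny_table()
  expect_identical(impute_missing(full, seed = 1)$data, full$data)

  tab$data$y <- NA_real_
  expect_error(impute_missing(tab, seed = 1), "entirely missing")
})

test_that("train/test splits are sized, disjoint, reproducible, and validated", {
  ds <- small_study(seed = 2, n = 100)
  sp <- split_train_test(ds$table, 0.3, seed = 9)
  expect_length(sp$test, 30)
  expect_length(sp$train, 70)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ds$table$gene_ids)
  expect_identical(split_train_test(ds$table, 0.3, seed = 9), sp)
  expect_false(identical(split_train_test(ds$table, 0.3, seed = 10)$test,
                         sp$test))

  two <- feature_table(data.frame(a = c(1, 2)), c("g1", "g2"),
                       c(a = "other"), c(a = "continuous"),
                       responses = data.frame(dN = c(0.1, 0.2)))
  expect_error(split_train_test(two, 0.999, seed = 1), "empty")
})
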