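test_that("the full schema encodes to 36 columns with paired transforms", {
  coh <- random_cohort(default_schema(), n = 5, seed = 1)
  feats <- encode_features(coh)
  expect_equal(ncol(feats$values), 36)
  expect_equal(sum(feats$columns$transform == "identity"), 19)
  expect_equal(sum(feats$columns$transform == "log1p"), 17)
  # each continuous attribute contributes exactly one pair
  cont <- default_schema()$name[default_schema()$kind == "continuous"]
  for (nm in cont) {
    expect_setequal(feats$columns$transform[feats$columns$source == nm],
                    c("identity", "log1p"))
  }
  # spot-check the log1p formula
  i <- which(feats$columns$name == "missense_snv_count_log1p")
  expect_equal(feats$values[, i],
               log1p(coh$data$missense_snv_count),
               ignore_attr = TRUE)
})

test_that("column-count formula holds over random schemas", {
  for (seed in 1:12) {
    s <- random_schema(seed)
    coh <- random_cohort(s, n = 4, seed = seed)
    feats <- encode_features(coh)
    expect_equal(ncol(feats$values),
                 sum(s$kind == "binary") + 2 * sum(s$kind == "continuous"))
    expect_equal(feats$columns$category,
                 s$category[match(feats$columns$source, s$name)])
  }
})

test_that("category restriction equals column-filtered full encoding", {
  coh <- random_cohort(default_schema(), n = 6, seed = 3)
  full <- encode_features(coh)
  for (cat in c("clinical", "tumor", "circulating")) {
    only <- encode_features(coh, cat)
    keep <- full$columns$category == cat
    expect_equal(only$values, full$values[, keep, drop = FALSE])
    expect_equal(only$columns, full$columns[keep, ],
                 ignore_attr = TRUE)
  }
})

test_that("missing attribute values propagate to both derived columns", {
  coh <- random_cohort(default_schema(), n = 6, seed = 4)
  coh$data$age[2] <- NA
  coh <- validate_cohort(coh)
  feats <- encode_features(coh)
  expect_true(is.na(feats$values[2, "age"]))
  expect_true(is.na(feats$values[2, "age_log1p"]))
  expect_equal(sum(is.na(feats$values)), 2)
})

test_that("preprocessor medians follow the midpoint convention", {
  m <- structure(list(
    values = cbind(a = c(1, 2, 9), b = c(1, 3, NA)),
    columns = data.frame(name = c("a", "b"), source = c("a", "b"),
                         transform = "identity", category = "tumor",
                         stringsAsFactors = FALSE)),
    class = "expn_features")
  pp <- fit_preprocessor(m)
  expect_equal(pp$medians, c(2, 2))

  # all-missing column is unimputable
  m$values[, "b"] <- NA
  expect_error(fit_preprocessor(m), "no non-missing")
})

test_that("applying a preprocessor centers, scales and fills gaps", {
  coh <- random_cohort(default_schema(), n = 10, seed = 5,
                       missing_rate = 0.1)
  feats <- encode_features(coh)
  pp <- fit_preprocessor(feats)
  out <- apply_preprocessor(pp, feats)
  expect_false(anyNA(out$values))
  expect_equal(unname(colMeans(out$values)), rep(0, 36),
               tolerance = 1e-12)
  # population-sd scaling: non-constant columns have sd sqrt(n/(n-1))
  sds <- apply(out$values, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(unname(sds[sds > 1e-9]),
               rep(1, sum(sds > 1e-9)), tolerance = 1e-12)

  # a held-out row's missing cell equals the training median, post-scaling
  held <- encode_features(random_cohort(default_schema(), n = 2,
                                        seed = 6))
  held$values[1, "age"] <- NA
  tr <- apply_preprocessor(pp, held)
  j <- which(pp$columns$name == "age")
  expect_equal(tr$values[1, "age"],
               (pp$medians[j] - pp$centers[j]) / pp$scales[j],
               ignore_attr = TRUE)

  # unfitted or mismatched inputs are refused
  bad <- pp
  bad$fitted <- FALSE
  expect_error(apply_preprocessor(bad, feats), "not fitted")
  sub <- encode_features(coh, "tumor")
  expect_error(apply_preprocessor(pp, sub), "does not match")
})

test_that("a constant training column maps to all zeros (scale guard)", {
  m <- structure(list(
    values = cbind(a = c(5, 5, 5, 5), b = c(1, 2, 3, 4)),
    columns = data.frame(name = c("a", "b"), source = c("a", "b"),
                         transform = "identity", category = "clinical",
                         stringsAsFactors = FALSE)),
    class = "expn_features")
  pp <- fit_preprocessor(m)
  expect_equal(pp$scales[1], 1)
  out <- apply_preprocessor(pp, m)
  expect_equal(out$values[, "a"], rep(0, 4), ignore_attr = TRUE)
})

test_that("preprocessing a held-out row never uses that row (leakage)", {
  coh <- random_cohort(default_schema(), n = 12, seed = 7,
                       missing_rate = 0.1)
  feats <- encode_features(coh)
  train <- subset_rows <- 1:11
  pp <- fit_preprocessor(structure(
    list(values = feats$values[train, ], columns = feats$columns),
    class = "expn_features"))

  held <- structure(list(values = feats$values[12, , drop = FALSE],
                         columns = feats$columns),
                    class = "expn_features")
  out1 <- apply_preprocessor(pp, held)$values

  # perturb the held-out row wildly; its transform must change only
  # through its own values, and the preprocessor must be unchanged
  held2 <- held
  held2$values[1, ] <- held2$values[1, ] * 100 + 7
  pp2 <- fit_preprocessor(structure(
    list(values = feats$values[train, ], columns = feats$columns),
    class = "expn_features"))
  expect_equal(pp2$medians, pp$medians)
  expect_equal(pp2$centers, pp$centers)
  expect_equal(pp2$scales, pp$scales)
  out2 <- apply_preprocessor(pp2, held)$values
  expect_equal(out1, out2)
})

test_that("feature matrices serialize with a metadata sidecar", {
  coh <- random_cohort(default_schema(), n = 4, seed = 8)
  feats <- encode_features(coh)
  path <- file.path(tempdir(), "features.tsv")
  write_features(feats, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".cols.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$name, feats$columns$name)
  unlink(c(path, paste0(path, ".cols.json")))
})
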