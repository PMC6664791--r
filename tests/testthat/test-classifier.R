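test_that("feature assembly has the published column counts", {
  set.seed(31)
  seqs <- lapply(1:3, function(i) random_rna_seq(paste0("s", i), 173))
  expect_equal(ncol(assemble_features(seqs, "global-kmer")), 340)
  expect_equal(ncol(assemble_features(seqs, "local-kmer")), 5440)
  stub <- structure(list(name = "flat", fold_fun = function(s)
    fold_result(strrep(".", s$length), 0, "flat")), class = "folding_engine")
  st <- assemble_features(seqs, "structural", engine = stub, N = 2)
  expect_equal(ncol(st), 33)
  both <- assemble_features(seqs, c("global-kmer", "structural"),
                            engine = stub, N = 2)
  expect_equal(ncol(both), 373)
  expect_equal(anyDuplicated(colnames(both)), 0L)
  expect_equal(rownames(both), c("s1", "s2", "s3"))
  expect_error(assemble_features(seqs, "structural"), "config error")
  expect_error(assemble_features(seqs, "bogus"), "config error")
})

test_that("train/validation split is seeded, disjoint and exhaustive", {
  tab <- data.frame(x = 1:20872)
  sp <- split_train_validation(tab, 0.9, rng_seed = 1)
  expect_length(sp$train, 18784)
  expect_length(sp$validation, 2088)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), 1:20872)
  expect_identical(split_train_validation(tab, 0.9, rng_seed = 1), sp)

  sp5 <- split_train_validation(data.frame(x = 1:10), 0.5, rng_seed = 2)
  expect_length(sp5$train, 5)
  expect_length(sp5$validation, 5)
  strat <- split_train_validation(data.frame(x = 1:100), 0.8, rng_seed = 3,
                                  stratify_by = rep(c("a", "b"), each = 50))
  expect_length(intersect(strat$train, 1:50), 40)
  expect_error(split_train_validation(data.frame(x = 1), 0.9), "degenerate")
  expect_error(split_train_validation(tab, 1.0), "fraction")
})

test_that("auc equals the exhaustive pair-counting oracle (n <= 20)", {
  expect_equal(auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(33)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(auc(y, s), auc_oracle(y, s))
  }
  expect_error(auc(rep(1, 5), runif(5)), "both classes")
})

test_that("a single depth-1 boosting round matches the closed-form oracle", {
  # 4 rows, 1 feature; no subsampling/regularization beyond lambda
  X <- matrix(c(1, 2, 10, 11), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(0, 0, 1, 1)
  lambda <- 1
  cfg <- model_config(eta = 1, lambda = lambda, max_depth = 1,
                      min_child_weight = 0, subsample = 1,
                      colsample_bytree = 1, nrounds = 1)
  m <- train_ires_model(X, y, cfg)
  # oracle: from base p = 0.5, g = p - y, h = p(1-p); split separates the
  # classes, leaf weight w = -G/(H + lambda)
  g <- 0.5 - y; h <- rep(0.25, 4)
  wl <- -sum(g[1:2]) / (sum(h[1:2]) + lambda)
  wr <- -sum(g[3:4]) / (sum(h[3:4]) + lambda)
  expect_equal(predict(m, X), plogis(c(wl, wl, wr, wr)))
})

test_that("training is deterministic, sized by nrounds, and validates input", {
  set.seed(34)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(X[, 1] + rnorm(50, 0, 0.3) > 0)
  cfg <- model_config(eta = 0.3, nrounds = 7, max_depth = 2,
                      min_child_weight = 1, rng_seed = 5)
  m1 <- train_ires_model(X, y, cfg)
  m2 <- train_ires_model(X, y, cfg)
  expect_length(m1$trees, 7)
  expect_identical(predict(m1, X), predict(m2, X))
  expect_true(all(predict(m1, X) >= 0 & predict(m1, X) <= 1))

  expect_error(train_ires_model(X, rep(1, 50), cfg), "both classes")
  expect_error(train_ires_model(X, y[-1], cfg), "length")
  expect_error(train_ires_model(unname(X), y, cfg), "column names")
  Xbad <- X; colnames(Xbad) <- paste0("g", 1:4)
  expect_error(predict(m1, Xbad), "schema error")
  expect_error(predict(m1, X[, c(2, 1, 3, 4)]), "schema error")
})

test_that("model serialization round-trips predictions bit-identically", {
  fx <- fixture_model(n_pos = 15, n_neg = 45, nrounds = 20, seed = 35)
  f <- withr::local_tempfile(fileext = ".json")
  save_ires_model(fx$model, f)
  back <- load_ires_model(f)
  expect_identical(predict(back, fx$matrix), predict(fx$model, fx$matrix))
  expect_equal(back$feature_names, fx$model$feature_names)
  expect_equal(back$config$eta, fx$model$config$eta)
  expect_error(load_ires_model(withr::local_tempfile(fileext = ".json",
                                                     lines = "{}")),
               "not an irescan model")
})

test_that("cross-validated grid search selects by mean held-out AUC", {
  set.seed(36)
  X <- matrix(rnorm(1000), 100, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(X[, 3] + rnorm(100, 0, 0.5) > 0)
  base <- model_config(nrounds = 25, min_child_weight = 1, eta = 0.2,
                       max_depth = 2)
  grid1 <- data.frame(eta = 0.2)
  res1 <- cross_validate_grid(X, y, grid1, folds = 10, rng_seed = 7,
                              base_cfg = base)
  expect_equal(nrow(res1$scores), 1)
  expect_equal(res1$best_config$eta, 0.2)
  expect_equal(res1$best_score, res1$scores$mean_auc[1])

  grid2 <- data.frame(eta = c(0.01, 0.3))
  res2 <- cross_validate_grid(X, y, grid2, folds = 5, rng_seed = 7,
                              base_cfg = base)
  expect_equal(res2$best_config$eta,
               grid2$eta[which.max(res2$scores$mean_auc)])
  expect_error(cross_validate_grid(X, y, grid1, folds = 101), "degenerate")
})

test_that("feature importance ranks the planted signal kmers at the top", {
  fx <- fixture_model(n_pos = 30, n_neg = 120, nrounds = 60, seed = 37)
  imp <- feature_importance(fx$model, top_k = 10)
  expect_lte(nrow(imp), 10)
  expect_true(all(diff(imp$gain) <= 0))
  expect_true(all(imp$gain >= 0))
  expect_true(any(imp$feature[1:10] %in% c("U", "UU", "UUU", "UUUU")))
  full <- feature_importance(fx$model, top_k = 1e6)
  expect_lte(nrow(full), length(fx$model$feature_names))
  expect_error(feature_importance(fx$model, top_k = 0), "top_k")
})

test_that("held-out AUC improves with sample size on planted signal", {
  aucs <- vapply(c(100, 300), function(n) {
    tab <- generate_synthetic_assay(round(n * 0.2), round(n * 0.8),
                                    rng_seed = 40 + n)
    tab <- assign_labels(tab, quiet = TRUE)
    m <- assemble_features(assay_sequences(tab))
    sp <- split_train_validation(tab, 0.8, rng_seed = 41,
                                 stratify_by = tab$label)
    cfg <- model_config(eta = 0.2, nrounds = 60, max_depth = 3,
                        min_child_weight = 2, rng_seed = 42)
    fit <- train_ires_model(m[sp$train, ], tab$label[sp$train], cfg)
    auc(tab$label[sp$validation], predict(fit, m[sp$validation, ]))
  }, numeric(1))
  expect_gte(aucs[2], aucs[1] - 0.05)  # monotone trend up to noise
  expect_gte(aucs[2], 0.8)
})
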