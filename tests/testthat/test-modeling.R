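# Splitting, clustering, folds, oversampling, metrics, CV, final models.

test_that("train/test split is 4:1, seeded, and reproducible", {
  x <- data.frame(i = 1:100)
  sp <- split_train_test(x, seed = 42)
  expect_equal(length(sp$train), 80L)
  expect_equal(length(sp$test), 20L)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(split_train_test(x, seed = 42), sp)
  expect_false(identical(split_train_test(x, seed = 43), sp))
})

test_that("butina clustering matches a brute-force oracle", {
  # degenerate: identical fingerprints form one cluster
  same <- matrix(rep(c(1L, 0L, 1L, 1L), each = 5), 5, 4)
  expect_equal(unique(butina_cluster(same, 0.3)), 1L)
  # all dissimilar: every compound a singleton
  eye <- diag(1L, 6)
  expect_equal(as.integer(butina_cluster(eye, 0.3)), 1:6)
  # two tight groups
  g <- rbind(matrix(rep(c(1L,1L,1L,0L,0L,0L), 3), 3, byrow = TRUE),
             matrix(rep(c(0L,0L,0L,1L,1L,1L), 3), 3, byrow = TRUE))
  cl <- butina_cluster(g, 0.5)
  expect_equal(length(unique(cl)), 2L)
  # random instances against the oracle
  for (seed in 1:5) {
    fp <- random_fp(15, d = 24, density = 0.3, seed = seed)
    expect_equal(as.integer(butina_cluster(fp, 0.3)), butina_oracle(fp, 0.3))
  }
  # radius contract: every member is >= floor similar to its centroid
  fp <- fx_small()$fp
  cl <- butina_cluster(fp, 0.3)
  cents <- attr(cl, "centroids")
  for (k in seq_along(cents)) {
    members <- which(cl == k)
    sims <- tanimoto_matrix(fp[members, , drop = FALSE],
                            fp[cents[k], , drop = FALSE])
    expect_true(all(sims >= 0.3))
  }
})

test_that("fold assignment keeps clusters together and balances sizes", {
  # five equal clusters spread over five folds
  plan <- assign_folds(rep(1:5, each = 10), k = 5, seed = 1)
  expect_equal(unname(table(plan$fold_id)), rep(10L, 5), ignore_attr = TRUE)
  # one giant cluster occupies a single fold
  plan1 <- assign_folds(rep(1L, 30), k = 5, seed = 1)
  expect_equal(length(unique(plan1$fold_id[1:30])), 1L)
  # greedy assignment: sizes {9,7,5,3,1}, k = 2 gives totals {13, 12}
  sizes <- c(9, 7, 5, 3, 1)
  plan2 <- assign_folds(rep(1:5, times = sizes), k = 2, seed = 7)
  expect_equal(sort(as.integer(table(plan2$fold_id))), c(12L, 13L))
  # property: spread bounded by largest cluster, clusters never split
  for (seed in 1:5) {
    cl <- sample(rep(1:8, times = c(1, 2, 3, 5, 8, 13, 21, 7)))
    p <- assign_folds(cl, k = 3, seed = seed)
    expect_true(all(tapply(p$fold_id, p$cluster_id,
                           function(f) length(unique(f))) == 1L))
    tot <- table(factor(p$fold_id, levels = 1:3))
    expect_lte(max(tot) - min(tot), 21)
  }
})

test_that("SMOTE balances classes by interpolation, preserving originals", {
  set.seed(1)
  x <- rbind(matrix(rnorm(90 * 4), 90, 4), matrix(rnorm(10 * 4, 5), 10, 4))
  y <- c(rep("inactive", 90), rep("active", 10))
  out <- smote_balance(x, y, seed = 3)
  expect_equal(unname(table(out$y)), c(90L, 90L), ignore_attr = TRUE)
  expect_identical(out$x[1:100, ], x)          # originals verbatim
  expect_equal(out$n_synthetic, 80L)
  # synthetic points interpolate within the minority range (1-D case)
  x1 <- matrix(c(rep(0.5, 8), 0, 1), ncol = 1)
  y1 <- c(rep("inactive", 8), rep("active", 2))
  o1 <- smote_balance(x1, y1, seed = 5)
  synth <- o1$x[-(1:10), 1]
  expect_true(all(synth >= 0 & synth <= 1))
  # balanced input unchanged
  bal <- smote_balance(x[c(1:10, 91:100), ], y[c(1:10, 91:100)])
  expect_equal(bal$n_synthetic, 0L)
  # nominal mode keeps binary features binary
  xb <- random_fp(30, d = 16, seed = 2)
  yb <- c(rep("inactive", 24), rep("active", 6))
  ob <- smote_balance(xb, yb, mode = "nominal", seed = 4)
  expect_true(all(ob$x %in% c(0, 1)))
  expect_error(smote_balance(x, rep("active", 100)), "two classes")
})

test_that("BEDROC hits its extremes and matches direct summation", {
  lab <- c(rep("active", 10), rep("inactive", 90))
  expect_equal(bedroc(seq(100, 1), lab, alpha = 20), 1.0)
  expect_equal(bedroc(seq(1, 100), lab, alpha = 20), 0.0)
  expect_error(bedroc(1:5, rep("active", 5)))
  set.seed(99)
  for (i in 1:25) {
    n <- sample(50:1000, 1)
    n_act <- sample(5:max(6, n %/% 5), 1)
    scores <- rnorm(n)
    active <- seq_len(n) %in% sample(n, n_act)
    alpha <- sample(c(5, 20, 80.5), 1)
    expect_equal(bedroc(scores, active, alpha),
                 bedroc_direct(scores, active, alpha), tolerance = 1e-9)
  }
})

test_that("BEDROC of random scores matches the analytic expectation", {
  # mean over trials should sit near the closed-form value for uniformly
  # random ranks: E[RIE] = 1, i.e. BEDROC_rand = (1 - RIE_min)/(RIE_max - RIE_min)
  n <- 1000; n_act <- 100; alpha <- 20
  lab <- c(rep(TRUE, n_act), rep(FALSE, n - n_act))
  denom <- (n_act / n) * (1 - exp(-alpha)) / (exp(alpha / n) - 1)
  rie_max <- sum(exp(-alpha * (1:n_act) / n)) / denom
  rie_min <- sum(exp(-alpha * ((n - n_act + 1):n) / n)) / denom
  expected <- (1 - rie_min) / (rie_max - rie_min)
  set.seed(7)
  vals <- replicate(200, bedroc(runif(n), lab, alpha))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("ROC-AUC equals exhaustive pair counting, ties at 1/2", {
  lab <- c(rep("active", 3), rep("inactive", 3))
  expect_equal(roc_auc(c(4, 5, 6, 1, 2, 3), lab), 1.0)
  expect_equal(roc_auc(rep(1, 6), lab), 0.5)
  set.seed(123)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    n_act <- sample(1:(n - 1), 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    active <- seq_len(n) %in% sample(n, n_act)
    expect_identical(roc_auc(scores, active), auc_pairs(scores, active))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(5)
    s <- rnorm(80); a <- rbinom(80, 1, 0.3) == 1
    expect_equal(roc_auc(s, a),
                 as.numeric(pROC::auc(pROC::roc(a, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("cv_select picks by mean BEDROC and respects the fold plan", {
  sm <- fx_small()
  sp <- split_train_test(sm$data, seed = 42)
  x <- sm$fp[sp$train, ]
  y <- sm$data$label[sp$train]
  # a one-point grid is chosen trivially
  cv1 <- cv_select(x, y, x, grid = list("sqrt"), k = 3, seed = 42,
                   n_trees = 200)
  expect_identical(cv1$best_max_features, "sqrt")
  # full grid: table covers every setting, each compound scored once
  cv <- cv_select(x, y, x, grid = list("sqrt", 0.2), k = 3, seed = 42,
                  n_trees = 200)
  expect_equal(nrow(cv$table), 2L)
  expect_false(anyNA(cv$oof_scores))
  expect_equal(cv$table$mean_bedroc,
               rowMeans(cv$table[, grep("^fold", names(cv$table))]))
  # planted-rule data beat a label-permuted control
  perm <- with_seed(99, sample(y))
  cv_perm <- cv_select(x, perm, x, grid = list(0.2), k = 3, seed = 42,
                       n_trees = 200)
  expect_gt(cv$best_mean_bedroc, cv_perm$best_mean_bedroc)
  # the shared fold plan never splits a Butina cluster
  p <- cv$fold_plan
  expect_true(all(tapply(p$fold_id, p$cluster_id,
                         function(f) length(unique(f))) == 1L))
})

test_that("final models are deterministic and memorize planted data", {
  sm <- fx_small()
  m1 <- train_final(sm$fp, sm$data$label, max_features = 0.2,
                    panel = "ecfp4_2048", n_trees = 300, seed = 42)
  m2 <- train_final(sm$fp, sm$data$label, max_features = 0.2,
                    panel = "ecfp4_2048", n_trees = 300, seed = 42)
  p1 <- predict(m1, sm$fp)
  expect_identical(p1, predict(m2, sm$fp))    # same manifest, same model
  expect_equal(m1$manifest$dataset_hash, m2$manifest$dataset_hash)
  # training actives score above 0.5 on memorizable data
  expect_true(all(p1[sm$data$true_active & sm$data$label == "active"] > 0.5))
  expect_error(predict(m1, "not_a_smiles"), "unparseable")
  # SMILES input is featurized according to the bundle's panel
  expect_equal(predict(m1, sm$data$smiles[1:3]), unname(p1[1:3]))
})

test_that("cross-source evaluation shows optimism and a clean null", {
  sm <- fx_small()
  sp <- split_train_test(sm$data, seed = 42)
  m <- train_final(sm$fp[sp$train, ], sm$data$label[sp$train], 0.2,
                   panel = "ecfp4_2048", n_trees = 300, seed = 42)
  self_eval <- cross_source_evaluate(m, sm$fp[sp$train, ],
                                     sm$data$label[sp$train])
  held_eval <- cross_source_evaluate(m, sm$fp[sp$test, ],
                                     sm$data$label[sp$test])
  expect_gte(self_eval$roc_auc, held_eval$roc_auc)
  perm <- with_seed(4, sample(sm$data$label[sp$train]))
  null_eval <- cross_source_evaluate(m, sm$fp[sp$train, ], perm)
  expect_lt(abs(null_eval$roc_auc - 0.5), 0.12)
  expect_error(cross_source_evaluate(m, sm$fp[1:5, ], rep("active", 5)),
               "both classes")
})
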