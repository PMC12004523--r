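# The synthetic data generator: determinism, contracts, learnability.

test_that("generation is deterministic and honors the class contract", {
  cfg <- synthetic_config(n_active = 40, n_inactive = 40, seed = 9,
                          label_noise = 0)
  d1 <- generate_labeled_dataset(cfg)
  d2 <- generate_labeled_dataset(cfg)
  expect_identical(d1, d2)
  expect_equal(sum(d1$true_active), 40L)
  # zero noise: observed label equals the planted-rule match everywhere
  expect_equal(d1$label == "active", d1$true_active)
  mols <- lbvscreen:::parse_mols(d1$smiles)
  hits <- lbvscreen:::smarts_count(mols, cfg$planted_rule) > 0
  expect_equal(unname(hits), d1$true_active)
  # different seed, different molecules
  d3 <- generate_labeled_dataset(synthetic_config(n_active = 40,
                                                  n_inactive = 40, seed = 10,
                                                  label_noise = 0))
  expect_false(identical(sort(d1$smiles), sort(d3$smiles)))
})

test_that("source profiles reproduce the assumed class ratios", {
  imb <- synthetic_config(n_total = 1200, source_profile = "imbalanced_score")
  expect_equal(imb$n_active / imb$n_inactive, 1 / 11, tolerance = 0.03)
  bal <- synthetic_config(n_total = 600, source_profile = "balanced_potency")
  expect_equal(bal$n_active / bal$n_inactive, 1.24, tolerance = 0.03)
  # explicit counts win
  cfg <- synthetic_config(n_active = 100, n_inactive = 1100,
                          source_profile = "imbalanced_score")
  expect_equal(cfg$n_active, 100)
  expect_equal(cfg$n_inactive, 1100)
})

test_that("activity payloads are consistent with observed labels", {
  pot <- generate_labeled_dataset(
    synthetic_config(n_total = 80, source_profile = "balanced_potency",
                     seed = 2))
  expect_true(all(pot$activity_value[pot$label == "active"] >= 6))
  expect_true(all(pot$activity_value[pot$label == "inactive"] < 6))
  sco <- generate_labeled_dataset(
    synthetic_config(n_total = 120, source_profile = "imbalanced_score",
                     seed = 2, excluded_band_fraction = 0.1))
  expect_true(all(sco$activity_value[sco$label == "active"] %in% 40:100))
  expect_true(all(sco$activity_value[sco$label == "inactive"] == 0))
  expect_true(all(sco$activity_value[sco$label == "excluded"] %in% 1:39))
  # curation drops exactly the ambiguous-band records
  cur <- curate_compounds(sco)
  expect_equal(nrow(cur$data), sum(sco$label != "excluded"))
})

test_that("generated molecules survive curation with zero rejections", {
  d <- fx_dataset(1)$data
  cur <- curate_compounds(d)
  expect_equal(nrow(cur$data), nrow(d))
  expect_identical(cur$data$smiles_std, cur$data$smiles)
})

test_that("scaffold clustering strength matches the requested structure", {
  cfg <- synthetic_config(n_active = 30, n_inactive = 30, seed = 4,
                          n_scaffolds = 5, decorations_per_scaffold = 12)
  d <- generate_labeled_dataset(cfg)
  s <- scaffold_clustering_strength(d)
  expect_gte(s$n_scaffolds_at_least, 5)
  expect_equal(sum(s$census$n_total), 60)
  # one decoration per scaffold: no analog series at all
  sparse <- generate_labeled_dataset(
    synthetic_config(n_active = 15, n_inactive = 15, seed = 4,
                     decorations_per_scaffold = 1))
  s2 <- scaffold_clustering_strength(sparse)
  expect_equal(s2$n_scaffolds_at_least, 0)
})

test_that("screening libraries keep ground truth and motif guarantees", {
  cfg <- synthetic_config(n_total = 100, seed = 6)
  lib0 <- generate_screening_library(60, 0, cfg)
  mols <- lbvscreen:::parse_mols(lib0$smiles)
  expect_true(all(lbvscreen:::smarts_count(mols, cfg$planted_rule) == 0))
  lib <- generate_screening_library(200, 20, cfg)
  expect_equal(sum(lib$true_active), 20L)
  expect_equal(nrow(lib), 220L)
  # every planted active carries a motif ring (azole/pyridine head groups)
  expect_true(all(cyp_motif_filter(lib$smiles[lib$true_active])))
  # planted liabilities are real: the filter catches them
  liab <- lib[lib$planted_liability %in%
                c("bromo", "iodo", "nitro", "basic_amine", "long_alkane"), ]
  if (nrow(liab) > 0) {
    expect_true(all(!liability_filter(liab$smiles)$pass))
  }
})

test_that("the planted signal is learnable and drowns at high noise", {
  clean <- generate_labeled_dataset(
    synthetic_config(n_total = 200, seed = 21, label_noise = 0))
  fp <- ecfp4(clean$smiles)
  sp <- split_train_test(clean, seed = 42)
  m <- train_final(fp[sp$train, ], clean$label[sp$train], 0.2,
                   panel = "ecfp4_2048", n_trees = 500, seed = 42)
  auc_clean <- roc_auc(predict(m, fp[sp$test, ]), clean$label[sp$test])
  expect_gt(auc_clean, 0.95)
  noisy <- generate_labeled_dataset(
    synthetic_config(n_total = 200, seed = 21, label_noise = 0.45))
  fpn <- ecfp4(noisy$smiles)
  mn <- train_final(fpn[sp$train, ], noisy$label[sp$train], 0.2,
                    panel = "ecfp4_2048", n_trees = 500, seed = 42)
  auc_noisy <- roc_auc(predict(mn, fpn[sp$test, ]), noisy$label[sp$test])
  expect_lt(abs(auc_noisy - 0.5), 0.2)   # near-chance at near-coin-flip noise
  expect_gt(auc_clean, auc_noisy)
})
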