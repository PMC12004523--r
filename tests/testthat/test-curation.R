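# Structure standardization, labeling, filtering, deduplication.

test_that("standardization strips salts, removes stereo, rejects garbage", {
  # salt stripping keeps one neutral parent
  expect_equal(standardize_structure("CC(=O)O.[Na+].[O-]C(C)=O")$smiles_std,
               "CC(=O)O")
  # stereo removal: enantiomer spelling collapses onto the flat parent
  flat <- standardize_structure("CC(N)C(=O)O")$smiles_std
  expect_equal(standardize_structure("C[C@H](N)C(=O)O")$smiles_std, flat)
  expect_equal(standardize_structure("C[C@@H](N)C(=O)O")$smiles_std, flat)
  # cis/trans marks removed
  expect_equal(standardize_structure("C/C=C/C")$smiles_std,
               standardize_structure("CC=CC")$smiles_std)
  # rejections carry reasons, never raise
  expect_equal(standardize_structure("not_a_smiles")$reason, "unparseable")
  expect_equal(standardize_structure("")$reason, "unparseable")
  expect_equal(standardize_structure("[Na+].[Cl-]")$reason,
               "empty-after-stripping")
})

test_that("charge neutralization fixes simple ions, preserves nitro", {
  expect_equal(standardize_structure("CC(=O)[O-]")$smiles_std, "CC(=O)O")
  expect_equal(standardize_structure("C[NH3+]")$smiles_std, "CN")
  nitro <- standardize_structure("[O-][N+](=O)c1ccccc1")$smiles_std
  expect_match(nitro, "\\[N\\+\\]|N\\(=O\\)=O")  # charge-separated group intact
})

test_that("annular azole tautomers standardize to one representative", {
  a <- standardize_structure("Cc1c[nH]cn1")$smiles_std   # 4-methylimidazole
  b <- standardize_structure("Cc1cnc[nH]1")$smiles_std   # 5-methyl spelling
  expect_equal(a, b)
})

test_that("standardization is idempotent on a generated corpus", {
  d <- fx_dataset(1)$data
  cfg <- synthetic_config(n_total = 60, source_profile = "balanced_potency",
                          seed = 3, salt_fraction = 0.5)
  salted <- generate_labeled_dataset(cfg)
  corpus <- c(d$smiles, salted$smiles)
  expect_gte(length(corpus), 500)
  std1 <- standardize_structure(corpus)$smiles_std
  expect_false(anyNA(std1))
  std2 <- standardize_structure(std1)$smiles_std
  expect_identical(std2, std1)
})

test_that("element and molecular weight admission is enforced", {
  r <- element_weight_filter(c("c1ccccc1",                 # 78 Da: too light
                               "CCCC[Sn](CCCC)CCCC",       # organotin
                               "O=C(Nc1ccc2ccccc2c1)c1ccc(cc1)S(C)(=O)=O"))
  expect_equal(r$pass, c(FALSE, FALSE, TRUE))
  expect_equal(r$reason[1:2], c("mw-out-of-range", "disallowed-element"))
  # bounds are inclusive: a molecule passes when the bound equals its MW
  mw <- lbvscreen:::mol_weight(lbvscreen:::parse_mols("c1ccccc1"))
  expect_true(element_weight_filter("c1ccccc1", mw_min = mw, mw_max = mw)$pass)
})

test_that("potency and score labeling follow the activity cutoffs", {
  expect_equal(label_by_potency(c(6.0, 5.99, 9.0, 2.3)),
               c("active", "inactive", "active", "inactive"))
  expect_equal(label_by_score(c(0L, 70L, 35L, 40L, 100L, 1L, 39L)),
               c("inactive", "active", "excluded", "active", "active",
                 "excluded", "excluded"))
  expect_error(label_by_score(101))
  expect_error(label_by_potency(NaN))
})

test_that("deduplication keeps one per label group, drops conflicts", {
  rec <- data.frame(
    compound_id = c("b", "a", "c", "d", "e"),
    smiles_std = c("CCO", "CCO", "CCN", "CCN", "CCC"),
    label = c("active", "active", "active", "inactive", "inactive"),
    stringsAsFactors = FALSE)
  out <- deduplicate_records(rec)
  expect_equal(sort(out$data$smiles_std), c("CCC", "CCO"))
  # first representative by compound_id sort order
  expect_equal(out$data$compound_id[out$data$smiles_std == "CCO"], "a")
  expect_equal(out$reasons[["conflicting-labels"]], 2L)
  # idempotent and order-insensitive at the set level
  again <- deduplicate_records(out$data)
  expect_equal(again$data, out$data)
  shuffled <- deduplicate_records(rec[c(3, 5, 1, 4, 2), ])
  expect_equal(shuffled$data$smiles_std, out$data$smiles_std)
})

test_that("cross-source overlap counts shared structures by label", {
  a <- data.frame(smiles_std = c("CCO", "CCN", "CCC", "CCF"),
                  label = c("active", "active", "inactive", "active"))
  expect_equal(cross_source_overlap(a, a)[c("shared_active", "shared_inactive")],
               list(shared_active = 3L, shared_inactive = 1L))
  b <- data.frame(smiles_std = c("COC", "CNC"), label = c("active", "active"))
  expect_equal(unlist(cross_source_overlap(a, b)[1:3]),
               c(shared_active = 0L, shared_inactive = 0L, conflicting = 0L))
  c3 <- data.frame(smiles_std = c("CCO", "CCN", "CCC", "COO"),
                   label = c("active", "active", "inactive", "inactive"))
  ov <- cross_source_overlap(a, c3)
  expect_equal(ov$shared_active, 2L)
  expect_equal(ov$shared_inactive, 1L)
})

test_that("curation report reconciles counts at every stage", {
  cfg <- synthetic_config(n_total = 80, source_profile = "imbalanced_score",
                          seed = 5, salt_fraction = 0.2,
                          excluded_band_fraction = 0.1)
  raw <- generate_labeled_dataset(cfg)
  raw$smiles[1] <- "not_a_smiles"  # plant one rejection
  cur <- curate_compounds(raw)
  st <- cur$report$stages
  expect_true(all(st$n_out <= st$n_in))
  expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
  for (i in seq_len(nrow(st))) {
    rr <- cur$report$rejection_reasons[[st$stage[i]]]
    expect_equal(sum(rr), st$n_in[i] - st$n_out[i])
  }
  # curated records are clean: valid labels, admission filter passes
  expect_true(all(cur$data$label %in% c("active", "inactive")))
  expect_true(all(element_weight_filter(cur$data$smiles_std)$pass))
  expect_equal(anyDuplicated(cur$data$smiles_std), 0L)
  # standardization idempotence on the curated output
  expect_identical(standardize_structure(cur$data$smiles_std)$smiles_std,
                   cur$data$smiles_std)
})
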