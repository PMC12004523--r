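# The triage funnel predicates and the funnel report.

test_that("rule-of-five allows at most one violation", {
  r <- ro5_filter(c(
    "CC(=O)Nc1ccc(O)cc1",                 # drug-like: pass, 0 violations
    "CCCCCCCCCCCCCCCCCC",                 # logP only: exactly 1 violation
    paste0("OC(=O)", paste(rep("OCC", 14), collapse = ""),
           paste(rep("CC", 20), collapse = ""))))  # MW + HBA + logP
  expect_equal(r$pass, c(TRUE, TRUE, FALSE))
  expect_equal(r$n_violations[1:2], c(0L, 1L))
  expect_gte(r$n_violations[3], 2L)
})

test_that("CYP motif filter recognizes azoles and pyridine rings", {
  letrozole <- "N#Cc1ccc(C(c2ccc(C#N)cc2)n2cncn2)cc1"
  expect_equal(cyp_motif_filter(c(letrozole, "c1ccccc1", "c1ccncc1",
                                  "c1ccc(-n2ccnc2)cc1",
                                  "c1ccc(-n2ccnn2)cc1", "CCO")),
               c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("ensemble gate combines rank and strict probability cutoffs", {
  # small library, generous top_n: probability alone decides
  p <- matrix(0.9, 5, 4)
  expect_true(all(ensemble_gate(p, letters[1:5], top_n = 10, p_min = 0.7)))
  # probability exactly at the threshold is excluded (strict >)
  p07 <- matrix(0.70, 5, 4)
  expect_false(any(ensemble_gate(p07, letters[1:5], top_n = 10, p_min = 0.7)))
  # 3-compound fixture against brute-force predicate evaluation
  pm <- rbind(c(0.9, 0.1, 0.1, 0.1),
              c(0.8, 0.95, 0.2, 0.2),
              c(0.1, 0.2, 0.75, 0.1))
  ids <- c("a", "b", "c")
  keep <- ensemble_gate(pm, ids, top_n = 1, p_min = 0.7)
  oracle <- vapply(1:3, function(i) {
    in_top <- any(vapply(1:4, function(j) {
      ord <- order(-pm[, j], ids)
      which(ord == i) <= 1
    }, TRUE))
    in_top && max(pm[i, ]) > 0.7
  }, TRUE)
  expect_equal(keep, oracle)
})

test_that("novelty filter excludes candidates at or above the threshold", {
  known <- rbind(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  exact07 <- c(rep(1L, 7), rep(0L, 3))        # 7/10 = 0.7 exactly
  below <- c(rep(1L, 6), rep(0L, 4))          # 6/10 = 0.6
  cand <- rbind(known[1, ], exact07, below)
  res <- novelty_filter(cand, known, max_sim = 0.7)
  expect_equal(res$keep, c(FALSE, FALSE, TRUE))
  expect_equal(res$max_similarity, c(1.0, 0.7, 0.6))
  # empty known-actives set keeps everything
  all_kept <- novelty_filter(cand, known[0, , drop = FALSE])
  expect_true(all(all_kept$keep))
})

test_that("liability filter accumulates reasons per alert", {
  r <- liability_filter(c(
    "BrCCCCCCCCCCCCCCCC",                         # 1-bromohexadecane
    "O=[N+]([O-])c1ccc(cc1)-c1ccc2ccccc2c1",      # nitroaryl
    "CCN(CC)CCc1ccc(-c2ccncc2)cc1",               # basic tertiary amine
    "O=C(NC(C)c1ccc(cc1)-n1ccnc1)c1cc2cc(Cl)ccc2oc1=O"))  # clean candidate
  expect_false(r$pass[1])
  expect_setequal(intersect(r$reasons[[1]],
                            c("heavy-halogen", "long-alkane",
                              "rotatable-bonds")),
                  c("heavy-halogen", "long-alkane", "rotatable-bonds"))
  expect_true("nitro" %in% r$reasons[[2]])
  expect_true("basic-amine" %in% r$reasons[[3]])
  # the chloro-coumarin-imidazole amide chemotype survives every alert
  expect_true(r$pass[4])
  expect_length(r$reasons[[4]], 0)
  # azole motif never self-trips the basic-amine alert
  motif_only <- liability_filter("Cc1ccc(-n2ccnc2)cc1")
  expect_true(motif_only$pass)
})

test_that("PAINS alerts catch their chemotype families", {
  r <- liability_filter(c(
    "O=C1C=CC(=O)C=C1",                           # para-quinone
    "Oc1ccccc1O",                                 # catechol
    "S=C1SC(=Cc2ccccc2)C(=O)N1",                  # ene-rhodanine
    "OCc1ccccc1"))                                # benzyl alcohol: clean
  expect_false(r$pass[1])
  expect_true(any(startsWith(r$reasons[[1]], "pains:")))
  expect_false(r$pass[2])
  expect_false(r$pass[3])
  expect_true(r$pass[4])
})

test_that("diversity selection keeps one representative per cluster", {
  fp <- rbind(matrix(rep(c(1L,1L,1L,1L,0L,0L,0L,0L), 3), 3, byrow = TRUE),
              matrix(rep(c(0L,0L,0L,0L,1L,1L,1L,1L), 2), 2, byrow = TRUE))
  ids <- c("a1", "a2", "a3", "b1", "b2")
  probs <- c(0.8, 0.95, 0.9, 0.7, 0.7)
  div <- diversity_select(fp, ids, probs, diversity_sim = 0.6)
  expect_equal(length(div$representatives), 2L)
  expect_true("a2" %in% div$representatives)    # highest probability
  expect_true("b1" %in% div$representatives)    # probability tie: lowest id
  # mutually dissimilar survivors all kept
  eye <- diag(1L, 4)
  div2 <- diversity_select(eye, letters[1:4], rep(0.9, 4), 0.6)
  expect_equal(length(div2$representatives), 4L)
})

test_that("run_funnel produces nested survivor sets with full audit", {
  bx <- fx_bundles()
  cfg <- fx_dataset(1)$config
  lib <- generate_screening_library(250, 15, cfg)
  cur <- curate_compounds(lib)
  rep <- run_funnel(cur$data, bx$bundles,
                    known_active_smiles = bx$known_actives,
                    config = funnel_config())
  st <- rep$stages
  expect_equal(st$stage, c("ro5", "cyp_motif", "ensemble_gate", "novelty",
                           "liability", "diversity"))
  expect_true(all(st$n_out <= st$n_in))
  expect_equal(st$n_in[-1], st$n_out[-6])
  # nesting
  for (i in 2:6) {
    expect_true(all(rep$survivors[[i]] %in% rep$survivors[[i - 1]]))
  }
  # every removed compound carries exactly one first-failure stage
  removed <- setdiff(cur$data$compound_id, rep$survivors$diversity)
  expect_setequal(names(rep$first_failure), removed)
  expect_true(all(rep$first_failure %in% st$stage))
  # shortlist columns are complete
  expect_true(all(c("compound_id", "smiles_std", "max_probability",
                    "max_sim_to_actives", "cluster") %in%
                  colnames(rep$shortlist)))
  # empty library: all stages zero
  empty <- run_funnel(cur$data[0, ], bx$bundles, bx$known_actives,
                      funnel_config())
  expect_true(all(empty$stages$n_out == 0))
  # a library consisting only of known actives dies at the novelty stage
  known_lib <- data.frame(
    compound_id = paste0("K", seq_along(bx$known_actives[1:30])),
    smiles_std = bx$known_actives[1:30], stringsAsFactors = FALSE)
  rep_known <- run_funnel(known_lib, bx$bundles,
                          known_active_smiles = bx$known_actives,
                          config = funnel_config())
  expect_equal(rep_known$stages$n_out[rep_known$stages$stage == "novelty"], 0)
})
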