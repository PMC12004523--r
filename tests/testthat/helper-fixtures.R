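# Shared fixtures (computed once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A balanced potency-source dataset at the study scale, with fingerprints.
fx_dataset <- function(seed = 1) {
  fixture(paste0("ds", seed), function() {
    cfg <- synthetic_config(n_total = 600,
                            source_profile = "balanced_potency", seed = seed)
    d <- generate_labeled_dataset(cfg)
    list(config = cfg, data = d, fp = ecfp4(d$smiles))
  })
}

# A small dataset for fast unit tests.
fx_small <- function() {
  fixture("small", function() {
    cfg <- synthetic_config(n_total = 160,
                            source_profile = "balanced_potency", seed = 11)
    d <- generate_labeled_dataset(cfg)
    list(config = cfg, data = d, fp = ecfp4(d$smiles))
  })
}

# Four trained bundles (two sources x two panels) on n = 600 datasets,
# plus their feature blocks — shared by the funnel-scale tests.
fx_bundles <- function() {
  fixture("bundles", function() {
    pot <- fx_dataset(1)
    cfg_sco <- synthetic_config(n_total = 600,
                                source_profile = "imbalanced_score",
                                seed = 1001)
    sco <- generate_labeled_dataset(cfg_sco)
    feats <- list(
      pot = list(ecfp4_2048 = pot$fp, physchem_2d = physchem_panel(pot$data$smiles)),
      sco = list(ecfp4_2048 = ecfp4(sco$smiles), physchem_2d = physchem_panel(sco$smiles)))
    labels <- list(pot = pot$data$label, sco = sco$label)
    bundles <- list()
    for (src in c("pot", "sco")) {
      for (panel in c("ecfp4_2048", "physchem_2d")) {
        bundles[[paste(src, panel, sep = "_")]] <-
          train_final(feats[[src]][[panel]], labels[[src]],
                      max_features = 0.2, panel = panel, seed = 42)
      }
    }
    known_actives <- c(pot$data$smiles[pot$data$label == "active"],
                       sco$smiles[sco$label == "active"])
    list(bundles = bundles, known_actives = known_actives,
         sco_data = sco, feats = feats, labels = labels)
  })
}

# ---- independent oracles ----------------------------------------------------

# BEDROC by literal direct summation (no geometric series, no vectorized
# ranking shortcuts).
bedroc_direct <- function(scores, active, alpha) {
  n_total <- length(scores)
  ord <- order(-scores, seq_along(scores))
  rank_of <- integer(n_total)
  for (pos in seq_len(n_total)) rank_of[ord[pos]] <- pos
  n_act <- sum(active)
  denom <- (n_act / n_total) * (1 - exp(-alpha)) / (exp(alpha / n_total) - 1)
  s <- 0
  for (i in which(active)) s <- s + exp(-alpha * rank_of[i] / n_total)
  rie <- s / denom
  s_max <- 0
  for (r in 1:n_act) s_max <- s_max + exp(-alpha * r / n_total)
  s_min <- 0
  for (r in (n_total - n_act + 1):n_total) s_min <- s_min + exp(-alpha * r / n_total)
  (rie - s_min / denom) / ((s_max - s_min) / denom)
}

# ROC-AUC by exhaustive pair counting, ties = 1/2.
auc_pairs <- function(scores, active) {
  pos <- scores[active]
  neg <- scores[!active]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Sphere-exclusion clustering by direct re-implementation with explicit
# loops (same centroid policy: descending precomputed neighbor count,
# ties by input order).
butina_oracle <- function(fp, floor) {
  n <- nrow(fp)
  sim <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      inter <- sum(fp[i, ] == 1 & fp[j, ] == 1)
      uni <- sum(fp[i, ] == 1 | fp[j, ] == 1)
      sim[i, j] <- if (uni == 0) 1 else inter / uni
    }
  }
  nbr <- lapply(1:n, function(i) setdiff(which(sim[i, ] >= floor), i))
  counts <- vapply(nbr, length, 0L)
  assigned <- rep(NA_integer_, n)
  cid <- 0L
  for (i in order(-counts, 1:n)) {
    if (!is.na(assigned[i])) next
    cid <- cid + 1L
    members <- c(i, nbr[[i]][is.na(assigned[nbr[[i]]])])
    assigned[members] <- cid
  }
  assigned
}

# Random fingerprint-like binary matrix.
random_fp <- function(n, d = 64, density = 0.2, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * d, 1, density), n, d)
}
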