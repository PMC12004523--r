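# The virtual-screening triage funnel: rule-of-five, CYP motif, ensemble
# probability/rank gate, novelty, structural liabilities, diversity
# clustering — with a per-stage audit trail.

#' Funnel configuration
#'
#' Thresholds and SMARTS sets for [run_funnel()]. Defaults follow the
#' screening campaign the package implements: keep compounds ranked in the
#' top `top_n` by any model with probability strictly above `p_min`,
#' require novelty (max similarity to known actives strictly below
#' `novelty_max_sim`), exclude PAINS and structural liabilities, cap
#' rotatable bonds at `rotatable_bond_max`, and cluster survivors at
#' `diversity_sim` for diverse representative selection.
#'
#' @param top_n rank cutoff of the ensemble gate.
#' @param p_min strict lower probability bound of the ensemble gate.
#' @param novelty_max_sim strict upper bound on similarity to known actives.
#' @param diversity_sim Butina centroid similarity for diversity clustering.
#' @param rotatable_bond_max maximum allowed rotatable bonds.
#' @param motif_smarts named character vector of qualifying CYP-inhibitor
#'   ring motifs (any match passes).
#' @param pains_smarts named character vector of PAINS alerts; defaults to
#'   the curated set shipped with the package (representative alerts for
#'   the canonical PAINS chemotype families; a full published list can be
#'   supplied here).
#' @param long_alkane_min minimum length of an unbranched sp3 carbon chain
#'   counted as a "long alkane" liability.
#' @return a `funnel_config` list.
#' @export
funnel_config <- function(top_n = 10000,
                          p_min = 0.7,
                          novelty_max_sim = 0.7,
                          diversity_sim = 0.6,
                          rotatable_bond_max = 8,
                          motif_smarts = default_motif_smarts(),
                          pains_smarts = default_pains_smarts(),
                          long_alkane_min = 7) {
  stopifnot(top_n >= 1, p_min >= 0, p_min <= 1,
            novelty_max_sim >= 0, novelty_max_sim <= 1,
            diversity_sim >= 0, diversity_sim <= 1,
            rotatable_bond_max >= 0, long_alkane_min >= 2)
  for (p in c(motif_smarts, pains_smarts)) ob_smarts(p)  # validate early
  structure(list(top_n = top_n, p_min = p_min,
                 novelty_max_sim = novelty_max_sim,
                 diversity_sim = diversity_sim,
                 rotatable_bond_max = rotatable_bond_max,
                 motif_smarts = motif_smarts,
                 pains_smarts = pains_smarts,
                 long_alkane_min = long_alkane_min),
            class = "funnel_config")
}

#' Qualifying CYP-inhibitor ring motifs (imidazole, triazoles, pyridine)
#' @export
default_motif_smarts <- function() {
  c(imidazole = "c1cncn1",
    triazole_123 = "c1cnnn1",
    triazole_124 = "c1ncnn1",
    pyridine = "c1ccncc1")
}

#' Curated PAINS-family alert SMARTS shipped with the package
#' @export
default_pains_smarts <- function() {
  path <- system.file("extdata", "pains_alerts.csv", package = "lbvscreen",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$smarts, df$name)
}

# ---- individual predicates --------------------------------------------------

#' Lipinski rule-of-five filter
#'
#' Pass iff at most one violation of: MW <= 500, logP <= 5, HBD <= 5,
#' HBA <= 10 (the original formulation allows one violation).
#'
#' @param smiles_std standardized SMILES vector.
#' @return data.frame with `pass` and `n_violations`.
#' @export
ro5_filter <- function(smiles_std) {
  mols <- parse_mols(smiles_std)
  stop_if_unparseable(mols, smiles_std, "ro5_filter")
  v <- (mol_weight(mols) > 500) +
       (mol_descriptor(mols, "logP") > 5) +
       (mol_descriptor(mols, "HBD") > 5) +
       (mol_descriptor(mols, "HBA1") > 10)
  data.frame(pass = v <= 1, n_violations = as.integer(v))
}

#' CYP-inhibitor motif filter
#'
#' Pass iff the molecule contains an aromatic imidazole, 1,2,3-/1,2,4-
#' triazole, or pyridine ring (the canonical heme-coordinating motifs).
#'
#' @param smiles_std standardized SMILES vector.
#' @param motif_smarts qualifying ring SMARTS.
#' @return logical vector.
#' @export
cyp_motif_filter <- function(smiles_std, motif_smarts = default_motif_smarts()) {
  mols <- parse_mols(smiles_std)
  stop_if_unparseable(mols, smiles_std, "cyp_motif_filter")
  hit <- rep(FALSE, length(mols))
  for (p in motif_smarts) hit <- hit | smarts_has(mols, p)
  hit
}

#' Ensemble probability/rank gate
#'
#' Keep a compound iff it ranks within the top `top_n` of at least one
#' model's descending-probability order (stable ties broken by compound
#' id) AND its maximum probability over the models strictly exceeds
#' `p_min`.
#'
#' @param probabilities numeric matrix, one column per model.
#' @param compound_ids ids used for deterministic tie-breaking.
#' @param top_n,p_min gate parameters.
#' @return logical vector of survivors.
#' @export
ensemble_gate <- function(probabilities, compound_ids,
                          top_n = 10000, p_min = 0.7) {
  p <- as.matrix(probabilities)
  stopifnot(nrow(p) == length(compound_ids),
            all(p >= 0 & p <= 1))
  in_top <- rep(FALSE, nrow(p))
  for (j in seq_len(ncol(p))) {
    ord <- order(-p[, j], compound_ids, method = "radix")
    ranks <- integer(nrow(p))
    ranks[ord] <- seq_len(nrow(p))
    in_top <- in_top | ranks <= top_n
  }
  in_top & apply(p, 1L, max) > p_min
}

#' Novelty filter against known actives
#'
#' Keep iff the maximum Tanimoto similarity to every known active is
#' strictly below `max_sim`. With no known actives everything is kept.
#'
#' @param candidate_fp,known_active_fp ECFP4 matrices.
#' @param max_sim strict threshold.
#' @return list with `keep` (logical) and `max_similarity`.
#' @export
novelty_filter <- function(candidate_fp, known_active_fp, max_sim = 0.7) {
  if (is.null(known_active_fp) || nrow(known_active_fp) == 0L) {
    return(list(keep = rep(TRUE, nrow(candidate_fp)),
                max_similarity = rep(0, nrow(candidate_fp))))
  }
  sims <- tanimoto_matrix(candidate_fp, known_active_fp)
  nn <- unname(apply(sims, 1L, max))
  list(keep = nn < max_sim, max_similarity = nn)
}

#' Structural liability filter
#'
#' Fails a compound, with accumulated reasons, on any of: a PAINS alert;
#' net positive formal charge; an unbranched chain of `long_alkane_min`
#' or more sp3 carbons; any bromine or iodine atom; a nitro group; a basic
#' aliphatic amine (primary/secondary/tertiary amine that is not an amide,
#' aniline or aromatic azole nitrogen — so the mandatory azole motif never
#' self-trips the filter); more than `rotatable_bond_max` rotatable bonds.
#'
#' @param smiles_std standardized SMILES vector.
#' @param config a [funnel_config()].
#' @return list with `pass` (logical) and `reasons` (list of character
#'   vectors).
#' @export
liability_filter <- function(smiles_std, config = funnel_config()) {
  mols <- parse_mols(smiles_std)
  stop_if_unparseable(mols, smiles_std, "liability_filter")
  n <- length(mols)
  reasons <- vector("list", n)
  add <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  for (nm in names(config$pains_smarts)) {
    add(smarts_has(mols, config$pains_smarts[[nm]]), paste0("pains:", nm))
  }
  charge <- vapply(mols, function(m) ob_fn("OBMol_GetTotalCharge")(m), 0)
  add(charge > 0, "positive-charge")
  add(smarts_has(mols, long_alkane_smarts(config$long_alkane_min)), "long-alkane")
  add(smarts_has(mols, "[#35,#53]"), "heavy-halogen")
  add(smarts_has(mols, "[$([NX3](=O)=O),$([NX3+](=O)[O-])]"), "nitro")
  add(smarts_has(mols, basic_amine_smarts()), "basic-amine")
  rot <- mol_descriptor(mols, "rotors")
  add(rot > config$rotatable_bond_max, "rotatable-bonds")
  list(pass = lengths(reasons) == 0L, reasons = reasons)
}

long_alkane_smarts <- function(min_len = 7) {
  mid <- paste(rep("[CX4H2]", max(0L, min_len - 2L)), collapse = "")
  paste0("[CX4;H2,H3]", mid, "[CX4;H2,H3]")
}

basic_amine_smarts <- function() {
  "[NX3;!$([NX3]C=[O,S,N]);!$([NX3]S(=O)=O);!$([NX3]c);!$([NX3+])]"
}

#' Diversity selection by Butina clustering
#'
#' Clusters survivors at `diversity_sim` and keeps one representative per
#' cluster: the compound with the highest ensemble probability (ties go to
#' the lexicographically smallest compound id).
#'
#' @param fp fingerprint matrix of the survivors.
#' @param compound_ids ids (tie-breaking and output).
#' @param max_probability per-compound max ensemble probability.
#' @param diversity_sim Butina centroid similarity.
#' @return list with `representatives` (ids), `cluster` (per compound).
#' @export
diversity_select <- function(fp, compound_ids, max_probability,
                             diversity_sim = 0.6) {
  if (nrow(fp) == 0L) {
    return(list(representatives = character(0), cluster = integer(0)))
  }
  cl <- butina_cluster(fp, similarity_floor = diversity_sim)
  reps <- vapply(split(seq_along(cl), cl), function(members) {
    ord <- order(-max_probability[members],
                 compound_ids[members], method = "radix")
    compound_ids[members[ord[1L]]]
  }, "")
  list(representatives = unname(reps), cluster = as.integer(cl))
}

stop_if_unparseable <- function(mols, smiles, where) {
  bad <- vapply(mols, is.null, TRUE)
  if (any(bad)) {
    stop("unparseable SMILES in ", where, "(): ",
         paste(utils::head(smiles[bad], 5), collapse = ", "))
  }
}

# ---- the funnel -------------------------------------------------------------

#' Run the full virtual-screening triage funnel
#'
#' Applies, in order: rule of five -> CYP motif -> ensemble
#' probability/rank gate -> novelty vs. known actives -> PAINS/liability
#' exclusion -> diversity clustering. Survivor sets are nested, every
#' removed compound carries its first failing stage (and detailed
#' liability reasons where applicable), and the result is an exported
#' ranked shortlist intended for downstream human triage (docking, visual
#' inspection), which is deliberately not automated here.
#'
#' @param library_records data.frame with `compound_id` and `smiles_std`
#'   (a standardized screening library).
#' @param bundles list of `screen_model` objects (typically four: two
#'   sources x two feature panels).
#' @param known_active_smiles standardized SMILES of known actives (for
#'   the novelty stage); may be `NULL`.
#' @param config a [funnel_config()].
#' @return a `funnel_report`.
#' @export
run_funnel <- function(library_records, bundles,
                       known_active_smiles = NULL,
                       config = funnel_config()) {
  stopifnot(all(c("compound_id", "smiles_std") %in% names(library_records)))
  if (anyDuplicated(library_records$compound_id)) {
    stop("library compound_id values must be unique")
  }
  ids <- as.character(library_records$compound_id)
  smiles <- library_records$smiles_std
  n0 <- length(ids)
  first_fail <- stats::setNames(rep(NA_character_, n0), ids)
  stages <- list()
  survivors <- list()
  alive <- rep(TRUE, n0)

  mark_stage <- function(stage, keep_alive) {
    removed <- alive & !keep_alive
    first_fail[removed] <<- stage
    alive <<- keep_alive
    stages[[stage]] <<- c(n_in = sum(removed) + sum(keep_alive),
                          n_out = sum(keep_alive))
    survivors[[stage]] <<- ids[keep_alive]
  }

  if (n0 == 0L) {
    return(new_funnel_report(
      data.frame(stage = funnel_stage_names(), n_in = 0L, n_out = 0L),
      list(), character(0), data.frame(), list()))
  }

  # stage 1: rule of five
  ro5 <- ro5_filter(smiles)
  mark_stage("ro5", alive & ro5$pass)

  # stage 2: CYP motif
  motif <- rep(FALSE, n0)
  motif[alive] <- cyp_motif_filter(smiles[alive], config$motif_smarts)
  mark_stage("cyp_motif", alive & motif)

  # stage 3: ensemble gate (featurize the gate population once per panel)
  probs <- matrix(NA_real_, n0, length(bundles))
  if (any(alive)) {
    idx <- which(alive)
    panel_cache <- list()
    for (b in seq_along(bundles)) {
      panel <- bundles[[b]]$manifest$panel
      if (is.null(panel_cache[[panel]])) {
        panel_cache[[panel]] <- switch(panel,
          ecfp4_2048 = ecfp4(smiles[idx]),
          physchem_2d = physchem_panel(smiles[idx]),
          stop("unsupported panel in funnel: ", panel))
      }
      probs[idx, b] <- predict(bundles[[b]], panel_cache[[panel]])
    }
  }
  gate <- rep(FALSE, n0)
  if (any(alive)) {
    idx <- which(alive)
    gate[idx] <- ensemble_gate(probs[idx, , drop = FALSE], ids[idx],
                               top_n = config$top_n, p_min = config$p_min)
  }
  mark_stage("ensemble_gate", alive & gate)

  # stage 4: novelty vs known actives
  max_sim <- rep(0, n0)
  nov <- rep(TRUE, n0)
  if (any(alive) && length(known_active_smiles) > 0) {
    idx <- which(alive)
    cand_fp <- ecfp4(smiles[idx])
    act_fp <- ecfp4(known_active_smiles)
    res <- novelty_filter(cand_fp, act_fp, max_sim = config$novelty_max_sim)
    nov[idx] <- res$keep
    max_sim[idx] <- res$max_similarity
  }
  mark_stage("novelty", alive & nov)

  # stage 5: liabilities (PAINS + structural alerts + rotatable bonds)
  liab_reasons <- vector("list", n0)
  liab_ok <- rep(FALSE, n0)
  if (any(alive)) {
    idx <- which(alive)
    liab <- liability_filter(smiles[idx], config)
    liab_ok[idx] <- liab$pass
    liab_reasons[idx] <- liab$reasons
  }
  mark_stage("liability", alive & liab_ok)

  # stage 6: diversity clustering, one representative per cluster
  shortlist <- data.frame()
  cluster_of <- rep(NA_integer_, n0)
  if (any(alive)) {
    idx <- which(alive)
    fp <- ecfp4(smiles[idx])
    max_p <- apply(probs[idx, , drop = FALSE], 1L, max)
    div <- diversity_select(fp, ids[idx], max_p,
                            diversity_sim = config$diversity_sim)
    cluster_of[idx] <- div$cluster
    keep_div <- alive
    keep_div[idx] <- ids[idx] %in% div$representatives
    mark_stage("diversity", keep_div)
    sl_idx <- which(keep_div)
    shortlist <- data.frame(
      compound_id = ids[sl_idx],
      smiles_std = smiles[sl_idx],
      stats::setNames(as.data.frame(probs[sl_idx, , drop = FALSE]),
                      paste0("prob_model", seq_along(bundles))),
      max_probability = apply(probs[sl_idx, , drop = FALSE], 1L, max),
      max_sim_to_actives = max_sim[sl_idx],
      cluster = cluster_of[sl_idx],
      stringsAsFactors = FALSE)
    shortlist <- shortlist[order(-shortlist$max_probability,
                                 shortlist$compound_id, method = "radix"), ]
    rownames(shortlist) <- NULL
  } else {
    mark_stage("diversity", alive)
  }

  stage_df <- data.frame(
    stage = names(stages),
    n_in = vapply(stages, `[[`, 0, "n_in"),
    n_out = vapply(stages, `[[`, 0, "n_out"),
    row.names = NULL, stringsAsFactors = FALSE)
  new_funnel_report(stage_df, survivors, first_fail[!is.na(first_fail)],
                    shortlist, liab_reasons = liab_reasons, ids = ids)
}

funnel_stage_names <- function() {
  c("ro5", "cyp_motif", "ensemble_gate", "novelty", "liability", "diversity")
}

new_funnel_report <- function(stage_df, survivors, first_fail, shortlist,
                              liab_reasons = list(), ids = character(0)) {
  structure(list(stages = stage_df,
                 survivors = survivors,
                 first_failure = first_fail,
                 shortlist = shortlist,
                 liability_reasons = stats::setNames(liab_reasons,
                                                     rep_len(ids, length(liab_reasons)))),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Virtual-screening funnel\n")
  for (i in seq_len(nrow(x$stages))) {
    st <- x$stages[i, ]
    cat(sprintf("  %-14s %7d -> %7d\n", st$stage, st$n_in, st$n_out))
  }
  cat(sprintf("shortlist: %d compounds\n", nrow(x$shortlist)))
  invisible(x)
}
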