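# Synthetic bioactivity datasets and screening libraries with a planted
# substructure rule, emulating the statistical structure of curated
# potency-source (ChEMBL-like) and score-source (PubChem-like) data:
# class balance / strong imbalance, clustered Murcko scaffolds, label
# noise, and non-trivial triage-funnel behavior.

# ---- grammar parts ----------------------------------------------------------

# Active-capable scaffold templates: a chromen-2-one (coumarin) core — the
# default planted rule — joined by a linker to a motif-bearing head group.
# Cores carry distinct baked-in ring substitutions and heads span distinct
# ring systems so that different active series fall into different Butina
# clusters at the 0.3 similarity floor (the analog-series structure real
# curated datasets show), while all series share the lactone environment
# that carries the planted signal.
synth_active_templates <- function() {
  cores <- c(cou_67 = "O=c1oc2ccc(%s)c(%s)c2cc1",
             cou_57 = "O=c1oc2cc(%s)c(%s)cc2cc1",
             cou_58 = "O=c1oc2c(%s)ccc(%s)c2cc1",
             cou_5_4 = "O=c1oc2cc(%s)ccc2c(%s)c1",
             cou_6_4 = "O=c1oc2ccc(%s)cc2c(%s)c1",
             cou_6me_4 = "O=c1oc2c(C)cc(%s)cc2c(%s)c1")
  linkers <- c(amide = "C(=O)N", sulfonamide = "S(=O)(=O)N",
               direct = "", methyl_amide = "C(=O)NC(C)",
               n_methyl_amide = "C(=O)N(C)")
  heads <- list(
    imidazolyl = list(smi = "-n1cc(%s)nc1", slots = 1L),
    triazolyl = list(smi = "-n1cc(%s)nn1", slots = 1L),
    phenyl_imidazole = list(smi = "c1ccc(cc1%s)-n1ccnc1", slots = 1L),
    pyridyl = list(smi = "c1ccc(%s)nc1", slots = 1L),
    benzimidazolyl = list(smi = "-c1nc2cc(%s)ccc2[nH]1", slots = 1L),
    phenyl_triazole = list(smi = "c1ccc(cc1%s)-n1ccnn1", slots = 1L)
  )
  combos <- expand.grid(core = names(cores), linker = names(linkers),
                        head = names(heads), stringsAsFactors = FALSE)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    core <- cores[[combos$core[r]]]
    link <- linkers[[combos$linker[r]]]
    head <- heads[[combos$head[r]]]
    smi_h <- head$smi
    if (link == "" && !startsWith(smi_h, "-")) link <- "-"
    if (nzchar(link) && !startsWith(link, "-") && startsWith(smi_h, "-")) {
      smi_h <- sub("^-", "", smi_h)  # N-C bond already explicit in linker
    }
    nm <- paste("coumarin", combos$core[r], combos$linker[r],
                combos$head[r], sep = "_")
    out[[nm]] <- list(template = paste0(core, link, smi_h),
                      slots = 2L + head$slots, motif = TRUE)
  }
  # fixed well-mixed order so neighboring indices differ in core, linker
  # and head (the training/foreign split takes alternating indices)
  out[with_seed(20260917L, sample(length(out)))]
}

# Decoy templates: no chromen-2-one anywhere. `motif` marks templates that
# carry an azole/pyridine ring so the motif gate stays non-trivial.
synth_decoy_templates <- function() {
  ring_b <- list(
    tolyl = list(smi = "c1ccc(cc1%s)C", motif = FALSE),
    naphthyl = list(smi = "c1ccc2cc(%s)ccc2c1", motif = FALSE),
    pyridyl = list(smi = "c1ccc(%s)nc1", motif = TRUE),
    phenylimidazole = list(smi = "c1ccc(cc1%s)-n1ccnc1", motif = TRUE),
    benzimidazolyl = list(smi = "-c1nc2cc(%s)ccc2[nH]1", motif = TRUE,
                          leading_bond = TRUE)
  )
  linkers <- c(amide = "C(=O)N", sulfonamide = "S(=O)(=O)N",
               ether = "O", methylene = "C", direct = "-")
  out <- list()
  for (l in names(linkers)) {
    for (rb in names(ring_b)) {
      part <- ring_b[[rb]]
      smi_b <- part$smi
      link <- linkers[[l]]
      if (isTRUE(part$leading_bond) && link == "-") smi_b <- sub("^-", "", smi_b)
      if (link == "-" && startsWith(smi_b, "-")) link <- ""
      tpl <- paste0("c1cc(%s)ccc1", link, smi_b)
      out[[paste("decoy", l, rb, sep = "_")]] <-
        list(template = tpl, motif = part$motif,
             slots = 1L + (part$slots %||% 2L) - 1L)
    }
  }
  out
}

# Decoration fragments (acyclic, liability-free, allowed elements only).
synth_subs_clean <- function() {
  c("C", "CC", "OC", "OCC", "F", "Cl", "O", "C#N", "C(F)(F)F", "OC(F)(F)F",
    "C(C)C", "CO", "C(=O)NC", "NC(C)=O", "S(C)(=O)=O", "C(C)=O",
    "C(=O)N(C)C", "OC(C)=O", "C(=O)NC(C)C", "S(=O)(=O)NC", "C(F)F",
    "OCC#N", "CC#N", "C(=O)O")
}

# Shifted decoration set for the "foreign source" variant (cross-source
# evaluation, screening libraries).
synth_subs_foreign <- function() {
  c("CCC", "OC(C)C", "CCO", "C(=O)NCC", "NC(=O)CC", "S(CC)(=O)=O",
    "C(=O)OC", "OC(F)F", "C(C)(C)C", "CC#N", "OCC(F)(F)F", "C(=O)N(C)C")
}

# Heavier fragments used when a draw lands below the 250 Da floor.
synth_subs_heavy <- function() {
  c("S(C)(=O)=O", "C(=O)NCC", "OC(F)(F)F", "C(=O)OCC", "NC(=O)C(C)C",
    "S(=O)(=O)N(C)C")
}

# Structural-liability fragments (screening-library decoys only).
synth_subs_liability <- function() {
  c(bromo = "Br", iodo = "I", nitro = "[N+](=O)[O-]",
    basic_amine = "CN(C)C", long_alkane = "CCCCCCCCC")
}

# Polyether tails that break two rule-of-five criteria at once
# (MW > 500 plus > 10 H-bond acceptors); several lengths for variety.
synth_sub_ro5_breaker <- function() {
  vapply(8:11, function(k) paste(rep("OCC", k), collapse = ""), "")
}

#' Default planted structure-activity rule: the chromen-2-one (coumarin)
#' lactone, written with kekulization-agnostic bond primitives.
#' @export
default_planted_rule <- function() {
  "[#8]=[#6]1~[#8]~[#6]2~[#6]~[#6]~[#6]~[#6]~[#6]2~[#6]~[#6]1"
}

# ---- configuration ----------------------------------------------------------

#' Configuration for the synthetic data generator
#'
#' The two source profiles emulate the class structure of curated
#' bioactivity sources: `balanced_potency` (continuous pChEMBL-like
#' potencies, about 1.2 active : 1 inactive) and `imbalanced_score`
#' (discrete 0-100 activity scores, about 1 active : 11 inactive). When
#' `n_active`/`n_inactive` are omitted they are derived from `n_total`
#' and the profile ratio.
#'
#' @param n_active,n_inactive requested class counts.
#' @param source_profile `"balanced_potency"` or `"imbalanced_score"`.
#' @param n_total convenience: total size from which class counts are
#'   derived via the profile ratio (ignored when explicit counts given).
#' @param planted_rule SMARTS whose presence defines true activity.
#' @param label_noise probability in \[0, 0.5) that an observed label (and
#'   its activity value) contradicts the planted rule.
#' @param n_scaffolds number of distinct scaffold templates to draw from;
#'   default `ceiling(n/decorations_per_scaffold)`.
#' @param decorations_per_scaffold target analogs per scaffold.
#' @param excluded_band_fraction extra score-source records carrying
#'   ambiguous scores (1-39) emitted on top of the requested counts;
#'   curation drops them. Default 0.
#' @param salt_fraction fraction of raw SMILES emitted with a
#'   counter-ion pair appended (exercises salt stripping). Default 0.
#' @param foreign use the shifted ("foreign source") template/decoration
#'   variant.
#' @param seed integer seed; identical config + seed gives identical
#'   output.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_active = NULL, n_inactive = NULL,
                             source_profile = c("balanced_potency",
                                                "imbalanced_score"),
                             n_total = 600,
                             planted_rule = default_planted_rule(),
                             label_noise = 0.1,
                             n_scaffolds = NULL,
                             decorations_per_scaffold = 25,
                             excluded_band_fraction = 0,
                             salt_fraction = 0,
                             foreign = FALSE,
                             seed = 1) {
  source_profile <- match.arg(source_profile)
  if (is.null(n_active) || is.null(n_inactive)) {
    ratio <- if (source_profile == "balanced_potency") 756 / 609 else 196 / 2152
    n_active <- round(n_total * ratio / (1 + ratio))
    n_inactive <- n_total - n_active
  }
  stopifnot(n_active >= 1, n_inactive >= 1,
            label_noise >= 0, label_noise < 0.5,
            excluded_band_fraction >= 0, excluded_band_fraction < 1,
            salt_fraction >= 0, salt_fraction <= 1)
  n <- n_active + n_inactive
  if (is.null(n_scaffolds)) {
    n_scaffolds <- max(2L, ceiling(n / decorations_per_scaffold))
  }
  ob_smarts(planted_rule)  # validate
  structure(list(n_active = n_active, n_inactive = n_inactive,
                 source_profile = source_profile,
                 planted_rule = planted_rule,
                 label_noise = label_noise,
                 n_scaffolds = n_scaffolds,
                 decorations_per_scaffold = decorations_per_scaffold,
                 excluded_band_fraction = excluded_band_fraction,
                 salt_fraction = salt_fraction,
                 foreign = foreign,
                 seed = seed),
            class = "synthetic_config")
}

# ---- generation internals ---------------------------------------------------

# Split the scaffold budget across classes proportionally and select the
# template subsets (foreign variants take the complementary halves so that
# foreign molecules live on different scaffolds than training molecules).
select_templates <- function(config) {
  act_all <- synth_active_templates()
  dec_all <- synth_decoy_templates()
  half <- function(x, second) {
    idx <- seq_along(x)
    pick <- if (second) idx[idx %% 2 == 0] else idx[idx %% 2 == 1]
    x[pick]
  }
  act <- half(act_all, config$foreign)
  dec <- half(dec_all, config$foreign)
  n <- config$n_active + config$n_inactive
  n_act_scaf <- max(1L, min(length(act),
                            round(config$n_scaffolds * config$n_active / n)))
  n_dec_scaf <- max(1L, min(length(dec), config$n_scaffolds - n_act_scaf))
  list(active = act[seq_len(n_act_scaf)],
       decoy = dec[seq_len(n_dec_scaf)])
}

subs_pool <- function(config) {
  if (config$foreign) synth_subs_foreign() else synth_subs_clean()
}

# Build one molecule from a template and decoration draws; retries until
# the parent parses, hits the 250-900 Da window, satisfies (or avoids) the
# planted rule, and is new. Returns the canonical SMILES.
build_molecule <- function(template, n_slots, want_rule, rule, pool,
                           used, extra_sub = NULL, max_tries = 40L) {
  for (try in seq_len(max_tries)) {
    subs <- sample(pool, n_slots, replace = TRUE)
    if (try > 10L) {
      heavy <- synth_subs_heavy()
      subs[1L] <- sample(heavy, 1L)
    }
    if (!is.null(extra_sub)) subs[n_slots] <- extra_sub
    smi <- do.call(sprintf, c(list(template), as.list(subs)))
    mol <- parse_mol(smi)
    if (is.null(mol)) next
    can <- mol_cansmi(mol)
    if (can %in% used) next
    mw <- ob_fn("OBMol_GetMolWt")(mol)
    if (mw < 250 || mw > 900) next
    hit <- smarts_count(list(mol), rule) > 0L
    if (hit != want_rule) next
    # emit the fully standardized form so curation is a strict no-op on
    # salt-free records (annular tautomer normalization may otherwise
    # relabel azole N-H placements)
    std <- standardize_one(can)$smiles
    if (is.na(std) || std %in% used) next
    return(std)
  }
  stop("synthetic generator failed to build a molecule from template: ",
       template)
}

# Deterministic per-family decoration subpools (strided windows over the
# fragment list), limiting decoration sharing between scaffold families.
family_subpools <- function(families, pool, width = 12L) {
  width <- min(width, length(pool))
  out <- vector("list", length(families))
  names(out) <- families
  for (fi in seq_along(families)) {
    idx <- ((fi - 1L) * 7L + seq_len(width) - 1L) %% length(pool) + 1L
    out[[fi]] <- pool[unique(idx)]
  }
  out
}

draw_potency <- function(active) {
  if (active) {
    repeat {
      v <- stats::rnorm(1, 7.0, 0.7)
      if (v >= 6) return(round(v, 2))
    }
  } else {
    repeat {
      v <- stats::rnorm(1, 5.0, 0.6)
      if (v < 6) return(round(v, 2))
    }
  }
}

# ---- public operations ------------------------------------------------------

#' Generate a labeled synthetic bioactivity dataset
#'
#' Molecules are composed from a scaffold x decoration grammar (azole /
#' pyridine / chromen-2-one / phenyl ring systems with a fixed acyclic
#' fragment list). A molecule is truly active iff it matches the planted
#' SMARTS rule; observed labels contradict the rule with probability
#' `label_noise`, and activity payloads are drawn consistently with the
#' observed label: potency sources get pChEMBL-like values (actives
#' ~ N(7.0, 0.7) truncated at >= 6, inactives ~ N(5.0, 0.6) truncated at
#' < 6), score sources get 0 for inactives and uniform 40-100 for actives.
#' All molecules pass element/molecular-weight curation by construction.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `compound_id`, `smiles`, `source`,
#'   `activity_value`, `label` (observed), `true_active` (ground truth),
#'   `scaffold_family`.
#' @export
generate_labeled_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tpl <- select_templates(config)
  pool <- subs_pool(config)
  prefix <- if (config$source_profile == "balanced_potency") "POT" else "SCO"
  if (config$foreign) prefix <- paste0("F", prefix)

  with_seed(config$seed, synth_rows(config, tpl, pool, prefix))
}

synth_rows <- function(config, tpl, pool, prefix) {
  n_act <- config$n_active
  n_ina <- config$n_inactive
  n <- n_act + n_ina
  n_extra <- if (config$source_profile == "imbalanced_score") {
    round(config$excluded_band_fraction * n)
  } else 0L

  truly_active <- c(rep(TRUE, n_act), rep(FALSE, n_ina),
                    rep(FALSE, n_extra))
  ntot <- length(truly_active)
  used <- character(0)
  smiles <- character(ntot)
  family <- character(ntot)
  act_names <- names(tpl$active)
  dec_names <- names(tpl$decoy)
  # Each scaffold family draws decorations from its own subpool: analog
  # series then differ between families not just in the ring system but in
  # the decoration chemistry, as real analog series do — and different
  # series land in different Butina clusters at the 0.3 floor.
  all_fams <- c(act_names, dec_names)
  subpool <- family_subpools(all_fams, pool)
  for (i in seq_len(ntot)) {
    if (truly_active[i]) {
      nm <- act_names[(i - 1L) %% length(act_names) + 1L]
      part <- tpl$active[[nm]]
      smi <- build_molecule(part$template, part$slots, TRUE,
                            config$planted_rule, subpool[[nm]], used)
    } else {
      nm <- dec_names[(i - 1L) %% length(dec_names) + 1L]
      part <- tpl$decoy[[nm]]
      smi <- build_molecule(part$template, part$slots, FALSE,
                            config$planted_rule, subpool[[nm]], used)
    }
    used <- c(used, smi)
    smiles[i] <- smi
    family[i] <- nm
  }

  flip <- stats::runif(ntot) < config$label_noise
  flip[seq_len(ntot) > n] <- FALSE  # ambiguous-band extras never flip
  observed_active <- xor(truly_active, flip)

  value <- numeric(ntot)
  label <- character(ntot)
  if (config$source_profile == "balanced_potency") {
    for (i in seq_len(ntot)) value[i] <- draw_potency(observed_active[i])
    label <- ifelse(observed_active, "active", "inactive")
  } else {
    is_extra <- seq_len(ntot) > n
    for (i in seq_len(ntot)) {
      value[i] <- if (is_extra[i]) {
        sample(1:39, 1L)
      } else if (observed_active[i]) {
        sample(40:100, 1L)
      } else 0
    }
    label <- ifelse(is_extra, "excluded",
                    ifelse(observed_active, "active", "inactive"))
  }

  raw <- smiles
  if (config$salt_fraction > 0) {
    salted <- stats::runif(ntot) < config$salt_fraction
    raw[salted] <- paste0(raw[salted], ".[Na+].[Cl-]")
  }

  out <- data.frame(
    compound_id = sprintf("%s-%05d", prefix, seq_len(ntot)),
    smiles = raw,
    source = if (config$source_profile == "balanced_potency") {
      "potency_source"
    } else "score_source",
    activity_value = value,
    label = label,
    true_active = truly_active,
    scaffold_family = family,
    stringsAsFactors = FALSE)
  # deterministic shuffle so classes are not block-ordered
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic screening library
#'
#' Decoys never match the planted rule; planted actives always do (built
#' from the foreign-variant active scaffolds so they are novel relative to
#' a training set generated with `foreign = FALSE`). Configurable decoy
#' fractions carry the CYP motif (via motif-bearing decoy scaffolds, so the
#' motif gate is non-trivial), structural liabilities, or a rule-of-five-
#' breaking polyether tail. Ground truth is retained in `true_active`.
#'
#' @param n_decoys,n_planted library composition.
#' @param config a [synthetic_config()] (its planted rule, seed and
#'   decoration variant are used).
#' @param liability_fraction fraction of decoys given a planted liability
#'   (bromine/iodine, nitro, basic amine or long alkane).
#' @param ro5_break_fraction fraction of decoys given the polyether tail.
#' @return data.frame with `compound_id`, `smiles`, `source`,
#'   `true_active`, `scaffold_family`, `planted_liability`.
#' @export
generate_screening_library <- function(n_decoys, n_planted, config,
                                       liability_fraction = 0.15,
                                       ro5_break_fraction = 0.08) {
  stopifnot(inherits(config, "synthetic_config"),
            n_decoys >= 0, n_planted >= 0)
  lib_cfg <- config
  lib_cfg$foreign <- TRUE
  tpl <- select_templates(lib_cfg)
  # decoys draw on every foreign decoy scaffold and the combined fragment
  # pool (a purchasable library is far more scaffold-diverse than one
  # curated bioactivity source); planted actives keep the foreign-only
  # fragments so they stay novel relative to a training set.
  all_foreign <- select_templates(
    utils::modifyList(config, list(foreign = TRUE, n_scaffolds = 1000L)))
  tpl$decoy <- all_foreign$decoy
  pool <- subs_pool(lib_cfg)
  decoy_pool <- unique(c(synth_subs_clean(), synth_subs_foreign()))
  liab <- synth_subs_liability()

  with_seed(config$seed + 7919L, {
    ntot <- n_decoys + n_planted
    truly_active <- c(rep(FALSE, n_decoys), rep(TRUE, n_planted))
    used <- character(0)
    smiles <- character(ntot)
    family <- character(ntot)
    liability <- character(ntot)
    act_names <- names(tpl$active)
    dec_names <- names(tpl$decoy)
    liab_draw <- stats::runif(ntot)
    for (i in seq_len(ntot)) {
      extra <- NULL
      if (truly_active[i]) {
        nm <- act_names[(i - 1L) %% length(act_names) + 1L]
        part <- tpl$active[[nm]]
        template <- part$template; slots <- part$slots
        liability[i] <- ""
      } else {
        nm <- dec_names[(i - 1L) %% length(dec_names) + 1L]
        part <- tpl$decoy[[nm]]
        template <- part$template; slots <- part$slots
        if (liab_draw[i] < liability_fraction) {
          pick <- sample(names(liab), 1L)
          extra <- liab[[pick]]
          liability[i] <- pick
        } else if (liab_draw[i] < liability_fraction + ro5_break_fraction) {
          extra <- sample(synth_sub_ro5_breaker(), 1L)
          liability[i] <- "ro5_polyether"
        } else {
          liability[i] <- ""
        }
      }
      smi <- build_molecule(template, slots, truly_active[i],
                            config$planted_rule,
                            if (truly_active[i]) pool else decoy_pool,
                            used, extra_sub = extra)
      used <- c(used, smi)
      smiles[i] <- smi
      family[i] <- nm
    }
    out <- data.frame(
      compound_id = sprintf("LIB-%06d", seq_len(ntot)),
      smiles = smiles,
      source = "library",
      true_active = truly_active,
      scaffold_family = family,
      planted_liability = liability,
      stringsAsFactors = FALSE)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Summarize the scaffold clustering structure of a generated dataset
#'
#' Verifies that generated data reproduce the assumed analog-series
#' structure: many compounds per Murcko scaffold.
#'
#' @param records data.frame with `smiles` (or `smiles_std`) and `label`.
#' @param min_members census threshold of interest.
#' @return list with `n_scaffolds`, `n_scaffolds_at_least` (scaffolds with
#'   `>= min_members` members), `largest`, `census`.
#' @export
scaffold_clustering_strength <- function(records, min_members = 10) {
  smiles <- records$smiles_std %||% records$smiles
  label <- records$label %||% rep("unlabeled", length(smiles))
  census <- scaffold_census(data.frame(smiles_std = smiles, label = label,
                                       stringsAsFactors = FALSE))
  list(n_scaffolds = nrow(census),
       n_scaffolds_at_least = sum(census$n_total >= min_members),
       largest = census$n_total[1],
       census = census)
}
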