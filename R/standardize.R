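# Structure standardization: salt stripping, neutralization, annular azole
# tautomer normalization, stereo removal, canonicalization.

#' Standardize a raw SMILES string
#'
#' Produces the canonical SMILES of the parent structure by applying, in
#' order: salt/solvent stripping (largest organic fragment kept),
#' charge neutralization where chemically valid (charge-separated groups
#' such as nitro and quaternary ammonium are preserved), canonical
#' selection among annular azole N-H tautomers, removal of all stereo
#' annotations, and canonicalization. The function is idempotent:
#' `standardize_structure(x$smiles)` returns `x$smiles` for any
#' successfully standardized `x`.
#'
#' @param smiles character vector of raw SMILES.
#' @return a data.frame with columns `smiles_raw`, `smiles_std`
#'   (`NA` on rejection) and `reason` (`""`, `"unparseable"` or
#'   `"empty-after-stripping"`).
#' @examples
#' \dontrun{
#' standardize_structure("CC(=O)O.[Na+]")$smiles_std  # "CC(=O)O"
#' }
#' @export
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles))
  std <- character(length(smiles))
  reason <- character(length(smiles))
  for (i in seq_along(smiles)) {
    r <- standardize_one(smiles[i])
    std[i] <- r$smiles
    reason[i] <- r$reason
  }
  data.frame(smiles_raw = smiles,
             smiles_std = ifelse(nzchar(reason), NA_character_, std),
             reason = reason,
             stringsAsFactors = FALSE)
}

standardize_one <- function(smi) {
  rej <- function(why) list(smiles = NA_character_, reason = why)
  if (is.na(smi) || !nzchar(trimws(smi))) return(rej("unparseable"))
  smi <- trimws(smi)
  if (is.null(parse_mol(smi))) return(rej("unparseable"))
  parent <- strip_salt_components(smi)
  if (is.na(parent)) return(rej("empty-after-stripping"))
  neutral <- neutralize_charges(parent)
  taut <- canonical_azole_tautomer(neutral)
  flat <- strip_stereo(taut)
  if (is.na(flat)) return(rej("unparseable"))
  list(smiles = flat, reason = "")
}

#' Keep the largest organic fragment of a multi-component SMILES
#'
#' Components are ranked by (contains carbon, heavy atom count, molecular
#' weight, canonical SMILES) so the choice is deterministic. Returns `NA`
#' when no component contains carbon (nothing organic survives stripping).
#' @keywords internal
strip_salt_components <- function(smi) {
  comps <- strsplit(smi, ".", fixed = TRUE)[[1]]
  comps <- comps[nzchar(comps)]
  if (length(comps) == 0L) return(NA_character_)
  if (length(comps) == 1L) return(cansmi(comps))
  info <- lapply(comps, function(cp) {
    mol <- parse_mol(cp)
    if (is.null(mol)) return(NULL)
    z <- mol_atomic_numbers(mol)
    list(smi = mol_cansmi(mol), organic = any(z == 6L),
         heavy = sum(z > 1L), mw = ob_fn("OBMol_GetMolWt")(mol))
  })
  info <- Filter(Negate(is.null), info)
  if (length(info) == 0L) return(NA_character_)
  organic <- Filter(function(x) x$organic, info)
  if (length(organic) == 0L) return(NA_character_)
  heavy <- vapply(organic, `[[`, 0, "heavy")
  mw <- vapply(organic, `[[`, 0, "mw")
  smis <- vapply(organic, `[[`, "", "smi")
  pick <- order(-heavy, -mw, smis)[1L]
  smis[pick]
}

#' Neutralize +1/-1 charges where chemically valid
#'
#' Uses OpenBabel's `neutralize` operation, which protonates anions
#' (carboxylates, phenolates, thiolates) and deprotonates protonated
#' amines while leaving charge-separated groups (nitro, N-oxides,
#' quaternary nitrogen) untouched.
#' @keywords internal
neutralize_charges <- function(smi) {
  mol <- parse_mol(smi)
  if (is.null(mol)) return(smi)
  if (is.null(.ob$neutralize)) .ob$neutralize <- ob_fn("OBOp_FindType")("neutralize")
  ob_fn("OBOp_Do")(.ob$neutralize, mol)
  mol_cansmi(mol)
}

#' Canonical annular azole tautomer
#'
#' Enumerates placements of aromatic N-H hydrogens over the aromatic
#' nitrogen positions of the molecule (swapping `[nH]` with `n` tokens of
#' the canonical SMILES), keeps formula-preserving parseable variants and
#' returns the lexicographically smallest canonical SMILES, iterated to a
#' fixpoint. Equivalent 1H/3H-azole spellings therefore standardize to one
#' representative. Non-annular (e.g. keto-enol) tautomerism is out of scope.
#' @keywords internal
canonical_azole_tautomer <- function(smi, max_iter = 8L) {
  cur <- cansmi(smi)
  if (is.na(cur)) return(smi)
  formula_of <- function(s) {
    m <- parse_mol(s)
    if (is.null(m)) NA_character_ else ob_fn("OBMol_GetFormula")(m)
  }
  target <- formula_of(cur)
  for (iter in seq_len(max_iter)) {
    nh_pos <- gregexpr("[nH]", cur, fixed = TRUE)[[1]]
    if (nh_pos[1L] == -1L) return(cur)
    n_pos <- bare_aromatic_n_positions(cur)
    if (length(n_pos) == 0L) return(cur)
    cands <- cur
    for (p in nh_pos) {
      for (q in n_pos) {
        cand <- swap_nh(cur, p, q)
        cs <- cansmi(cand)
        if (is.na(cs) || !identical(formula_of(cs), target)) next
        cands <- c(cands, cs)
      }
    }
    best <- sort(unique(cands), method = "radix")[1L]  # C-locale ordering
    if (identical(best, cur)) return(cur)
    cur <- best
  }
  cur
}

# Positions of bare aromatic 'n' atoms (not inside brackets) in a SMILES.
bare_aromatic_n_positions <- function(smi) {
  chars <- strsplit(smi, "", fixed = TRUE)[[1]]
  depth <- 0L
  pos <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "[") depth <- depth + 1L
    else if (ch == "]") depth <- depth - 1L
    else if (depth == 0L && ch == "n") pos <- c(pos, i)
  }
  pos
}

swap_nh <- function(smi, nh_start, n_pos) {
  # nh_start indexes the '[' of an '[nH]' token; n_pos a bare 'n'.
  stopifnot(substr(smi, nh_start, nh_start + 3L) == "[nH]")
  if (n_pos > nh_start) {
    paste0(substr(smi, 1L, nh_start - 1L), "n",
           substr(smi, nh_start + 4L, n_pos - 1L), "[nH]",
           substr(smi, n_pos + 1L, nchar(smi)))
  } else {
    paste0(substr(smi, 1L, n_pos - 1L), "[nH]",
           substr(smi, n_pos + 1L, nh_start - 1L), "n",
           substr(smi, nh_start + 4L, nchar(smi)))
  }
}

#' Remove stereochemical annotations from a SMILES
#'
#' Drops tetrahedral (`@`) marks and double-bond configuration (`/`, `\`)
#' at the string level, then re-canonicalizes.
#' @keywords internal
strip_stereo <- function(smi) {
  flat <- gsub("@", "", gsub("[/\\\\]", "", smi))
  cansmi(flat)
}

#' Element and molecular-weight admission filter
#'
#' A curated compound must contain only the common organic elements
#' H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I and have an average parent
#' molecular weight in the inclusive range \[250, 900\] Da.
#'
#' @param smiles_std character vector of standardized SMILES.
#' @param mw_min,mw_max inclusive molecular-weight bounds in Da.
#' @return data.frame with columns `pass` (logical) and `reason`
#'   (`""`, `"disallowed-element"` or `"mw-out-of-range"`).
#' @export
element_weight_filter <- function(smiles_std, mw_min = 250, mw_max = 900) {
  allowed <- c(1L, 5L, 6L, 7L, 8L, 9L, 14L, 15L, 16L, 17L, 34L, 35L, 53L)
  pass <- logical(length(smiles_std))
  reason <- character(length(smiles_std))
  for (i in seq_along(smiles_std)) {
    mol <- parse_mol(smiles_std[i])
    if (is.null(mol)) {
      pass[i] <- FALSE; reason[i] <- "unparseable"; next
    }
    z <- mol_atomic_numbers(mol)
    if (!all(z %in% allowed)) {
      pass[i] <- FALSE; reason[i] <- "disallowed-element"; next
    }
    mw <- ob_fn("OBMol_GetMolWt")(mol)
    if (mw < mw_min || mw > mw_max) {
      pass[i] <- FALSE; reason[i] <- "mw-out-of-range"; next
    }
    pass[i] <- TRUE
  }
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Label a compound from a pChEMBL-style potency value
#'
#' Potency is on the -log10 molar scale; 6 corresponds to 1 uM.
#' @param pchembl numeric vector.
#' @param threshold activity cutoff on the pChEMBL scale (default 6).
#' @return character vector, `"active"` (value >= 6) or `"inactive"`.
#' @export
label_by_potency <- function(pchembl, threshold = 6.0) {
  stopifnot(is.numeric(pchembl), all(is.finite(pchembl)))
  ifelse(pchembl >= threshold, "active", "inactive")
}

#' Label a compound from a PubChem-style 0-100 activity score
#'
#' Score 0 is inactive, scores in \[40, 100\] are active, everything else
#' (the ambiguous 1-39 band) is excluded from modeling.
#' @param score integer vector in \[0, 100\].
#' @return character vector in `c("active", "inactive", "excluded")`.
#' @export
label_by_score <- function(score) {
  stopifnot(is.numeric(score), all(score == as.integer(score)),
            all(score >= 0 & score <= 100))
  out <- rep("excluded", length(score))
  out[score == 0] <- "inactive"
  out[score >= 40 & score <= 100] <- "active"
  out
}
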