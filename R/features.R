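# Featurization: ECFP4 fingerprints, physicochemical descriptor panel,
# the 13-property PCA panel, Tanimoto similarity, nearest-neighbor profiles.

#' ECFP4 fingerprints (2048 bits)
#'
#' Extended-connectivity fingerprints of radius 2 computed by OpenBabel and
#' folded to 2048 bits (bitwise OR of the two 2048-bit halves of the raw
#' 4096-bit fingerprint). Deterministic; equivalent SMILES spellings of one
#' molecule give identical fingerprints.
#'
#' @param smiles_std character vector of standardized SMILES.
#' @return a `feature_block`: integer 0/1 matrix, one row per compound,
#'   2048 columns, with attributes `panel = "ecfp4_2048"` and `manifest`.
#' @export
ecfp4 <- function(smiles_std) {
  bad <- vapply(smiles_std, function(s) is.null(parse_mol(s)), TRUE)
  if (any(bad)) {
    stop("unparseable SMILES passed to ecfp4(): ",
         paste(utils::head(smiles_std[bad], 5), collapse = ", "))
  }
  raw <- ecfp4_raw(smiles_std)
  half <- ncol(raw) %/% 2L
  folded <- (raw[, seq_len(half), drop = FALSE] |
             raw[, half + seq_len(half), drop = FALSE]) * 1L
  feature_block(folded, panel = "ecfp4_2048",
                manifest = paste0("ecfp4_bit_", seq_len(half)),
                compound_ids = names(smiles_std))
}

feature_block <- function(matrix, panel, manifest, compound_ids = NULL) {
  stopifnot(ncol(matrix) == length(manifest))
  colnames(matrix) <- manifest
  if (!is.null(compound_ids)) rownames(matrix) <- compound_ids
  attr(matrix, "panel") <- panel
  class(matrix) <- c("feature_block", class(matrix))
  matrix
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("feature_block: %d compounds x %d features (panel %s)\n",
              nrow(x), ncol(x), attr(x, "panel")))
  invisible(x)
}

# ---- physicochemical panel --------------------------------------------------

panel_manifest_path <- function() {
  system.file("extdata", "physchem_manifest.csv", package = "lbvscreen",
              mustWork = TRUE)
}

#' The manifest of the physicochemical descriptor panel
#'
#' Each row defines one feature: `kind` is `descriptor` (an OpenBabel
#' descriptor), `graph` (a molecular-graph count) or `smarts` (unique
#' match count of a SMARTS pattern given in `arg`).
#' @return data.frame with columns `name`, `kind`, `arg`.
#' @export
physchem_manifest <- function() {
  utils::read.csv(panel_manifest_path(), stringsAsFactors = FALSE)
}

#' Physicochemical 2D descriptor panel
#'
#' Computes the manifest-pinned panel of two-dimensional physicochemical
#' descriptors (OpenBabel descriptors, molecular-graph counts and SMARTS
#' fragment counts). Non-finite values are replaced by the column median
#' of the finite entries (training-median imputation); an attribute
#' `imputed` records how many cells were touched.
#'
#' @param smiles_std character vector of standardized SMILES.
#' @return a `feature_block` with panel `"physchem_2d"`.
#' @export
physchem_panel <- function(smiles_std) {
  man <- physchem_manifest()
  mols <- parse_mols(smiles_std)
  bad <- vapply(mols, is.null, TRUE)
  if (any(bad)) {
    stop("unparseable SMILES passed to physchem_panel(): ",
         paste(utils::head(smiles_std[bad], 5), collapse = ", "))
  }
  graphs <- NULL  # computed lazily once if any graph feature is present
  out <- matrix(NA_real_, length(mols), nrow(man))
  for (j in seq_len(nrow(man))) {
    kind <- man$kind[j]
    arg <- man$arg[j]
    if (kind == "descriptor") {
      out[, j] <- mol_descriptor(mols, arg)
    } else if (kind == "smarts") {
      out[, j] <- as.numeric(smarts_count(mols, arg))
    } else if (kind == "graph") {
      if (is.null(graphs)) graphs <- lapply(mols, mol_graph)
      out[, j] <- vapply(graphs, graph_metric, 0, metric = arg)
    } else {
      stop("unknown manifest kind: ", kind)
    }
  }
  n_imputed <- 0L
  for (j in seq_len(ncol(out))) {
    bad <- !is.finite(out[, j])
    if (any(bad)) {
      med <- stats::median(out[!bad, j])
      if (!is.finite(med)) med <- 0
      out[bad, j] <- med
      n_imputed <- n_imputed + sum(bad)
    }
  }
  fb <- feature_block(out, panel = "physchem_2d", manifest = man$name,
                      compound_ids = names(smiles_std))
  attr(fb, "imputed") <- n_imputed
  fb
}

# One named scalar metric of a molecular graph (see mol_graph()).
graph_metric <- function(g, metric) {
  carbon <- g$z == 6L
  switch(metric,
    n_heavy_atoms = sum(g$z > 1L),
    n_hydrogens = sum(g$implicit_h) + sum(g$z == 1L),
    n_rings = max(0L, nrow(g$bonds) - g$n + 1L),
    n_ring_atoms = sum(g$in_ring),
    n_aromatic_atoms = sum(g$aromatic),
    frac_csp3 = if (any(carbon)) sum(carbon & g$hyb == 3L) / sum(carbon) else 0,
    n_sp3_carbons = sum(carbon & g$hyb == 3L),
    n_sp2_carbons = sum(carbon & g$hyb == 2L),
    n_sp_carbons = sum(carbon & g$hyb == 1L),
    sum_formal_charge = sum(g$charge),
    n_positive_atoms = sum(g$charge > 0L),
    n_negative_atoms = sum(g$charge < 0L),
    n_stereocenters_est = count_stereocenters(g),
    count_B = sum(g$z == 5L),
    count_C = sum(carbon),
    count_N = sum(g$z == 7L),
    count_O = sum(g$z == 8L),
    count_F = sum(g$z == 9L),
    count_Si = sum(g$z == 14L),
    count_P = sum(g$z == 15L),
    count_S = sum(g$z == 16L),
    count_Cl = sum(g$z == 17L),
    count_Se = sum(g$z == 34L),
    count_Br = sum(g$z == 35L),
    count_I = sum(g$z == 53L),
    stop("unknown graph metric: ", metric)
  )
}

#' Count candidate stereocenters on the heavy-atom graph
#'
#' Standardization strips stereo annotations, so this counts potential
#' tetrahedral centers: sp3 carbons whose four branches (heavy neighbors
#' plus implicit hydrogens) are pairwise distinct under two rounds of
#' Morgan-style neighborhood refinement. An approximation, used only as a
#' descriptor.
#' @keywords internal
count_stereocenters <- function(g) {
  if (g$n == 0L) return(0L)
  adj <- vector("list", g$n)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      f <- g$bonds[b, "from"]; t <- g$bonds[b, "to"]
      adj[[f]] <- c(adj[[f]], t)
      adj[[t]] <- c(adj[[t]], f)
    }
  }
  inv <- paste(g$z, g$charge, g$aromatic, g$implicit_h, sep = "/")
  for (round in 1:2) {
    inv <- vapply(seq_len(g$n), function(i) {
      paste(inv[i], paste(sort(inv[adj[[i]]]), collapse = ","), sep = "|")
    }, "")
  }
  count <- 0L
  for (i in seq_len(g$n)) {
    if (g$z[i] != 6L || g$hyb[i] != 3L) next
    branches <- c(inv[adj[[i]]], rep("H", g$implicit_h[i]))
    if (length(branches) == 4L && !anyDuplicated(branches)) count <- count + 1L
  }
  count
}

#' The 13-property panel used for chemical-space PCA
#'
#' Exactly, in order: number of nitrogen atoms, number of oxygen atoms,
#' number of (candidate) chiral centers, molecular weight, number of heavy
#' atoms, hydrogen-bond acceptors, hydrogen-bond donors, logP, topological
#' polar surface area, number of aromatic atoms, sum of formal charges,
#' number of rings, and the fraction of sp3-hybridized carbons.
#'
#' @param smiles_std character vector of standardized SMILES.
#' @return a `feature_block` with panel `"pca_panel_13"` (13 columns).
#' @export
pca_panel_13 <- function(smiles_std) {
  mols <- parse_mols(smiles_std)
  bad <- vapply(mols, is.null, TRUE)
  if (any(bad)) {
    stop("unparseable SMILES passed to pca_panel_13(): ",
         paste(utils::head(smiles_std[bad], 5), collapse = ", "))
  }
  graphs <- lapply(mols, mol_graph)
  gm <- function(metric) vapply(graphs, graph_metric, 0, metric = metric)
  out <- cbind(
    n_nitrogen = gm("count_N"),
    n_oxygen = gm("count_O"),
    n_chiral_centers = gm("n_stereocenters_est"),
    molecular_weight = mol_weight(mols),
    n_heavy_atoms = gm("n_heavy_atoms"),
    n_hba = mol_descriptor(mols, "HBA1"),
    n_hbd = mol_descriptor(mols, "HBD"),
    logp = mol_descriptor(mols, "logP"),
    tpsa = mol_descriptor(mols, "TPSA"),
    n_aromatic_atoms = gm("n_aromatic_atoms"),
    sum_formal_charge = gm("sum_formal_charge"),
    n_rings = gm("n_rings"),
    fraction_csp3 = gm("frac_csp3")
  )
  feature_block(out, panel = "pca_panel_13", manifest = colnames(out),
                compound_ids = names(smiles_std))
}

# ---- similarity -------------------------------------------------------------

#' Tanimoto similarity of two fingerprint bit vectors
#'
#' |a AND b| / |a OR b|. By convention two all-zero vectors have
#' similarity 1 (identical empty molecules), and an all-zero vector has
#' similarity 0 to any nonzero vector.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 1.0 else inter / uni
}

#' All-pairs Tanimoto similarity between two fingerprint matrices
#'
#' @param a,b 0/1 matrices with the same number of columns (rows are
#'   compounds).
#' @return `nrow(a)` x `nrow(b)` similarity matrix.
#' @export
tanimoto_matrix <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  stopifnot(ncol(a) == ncol(b))
  inter <- tcrossprod(a, b)
  ra <- rowSums(a); rb <- rowSums(b)
  uni <- outer(ra, rb, "+") - inter
  out <- ifelse(uni == 0, 1.0, inter / pmax(uni, 1e-300))
  out
}

#' Nearest-neighbor similarity profile between two compound sets
#'
#' For each query compound, its maximum Tanimoto similarity to the
#' reference set; the profile reports, over a threshold grid, the
#' proportion of query compounds whose nearest-neighbor similarity is at
#' least the threshold. The curve is monotone non-increasing.
#'
#' @param query_fp,reference_fp fingerprint matrices (same panel).
#' @param thresholds numeric grid in \[0, 1\].
#' @return list with `nn_similarity` (per-query max similarity) and
#'   `profile` (data.frame threshold/proportion).
#' @export
nn_profile <- function(query_fp, reference_fp,
                       thresholds = seq(0, 1, by = 0.05)) {
  sims <- tanimoto_matrix(query_fp, reference_fp)
  nn <- apply(sims, 1L, max)
  prop <- vapply(thresholds, function(t) mean(nn >= t), 0)
  list(nn_similarity = nn,
       profile = data.frame(threshold = thresholds, proportion = prop))
}
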