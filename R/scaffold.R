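# Bemis-Murcko scaffolds and the scaffold census.

#' Murcko scaffold of a molecule
#'
#' Bemis-Murcko framework: ring systems plus the linker atoms connecting
#' them, side chains removed; atoms double- or triple-bonded directly to
#' the framework (e.g. carbonyl oxygens on a linker) are retained. Acyclic
#' molecules map to the empty scaffold `""`.
#'
#' @param smiles_std character vector of standardized SMILES.
#' @return character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules, `NA` for unparseable input).
#' @export
murcko_scaffold <- function(smiles_std) {
  vapply(smiles_std, murcko_one, "", USE.NAMES = FALSE)
}

murcko_one <- function(smi) {
  mol <- parse_mol(smi)
  if (is.null(mol)) return(NA_character_)
  g <- mol_graph(mol)
  if (!any(g$in_ring)) return("")

  adj <- vector("list", g$n)
  bond_order <- vector("list", g$n)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      f <- g$bonds[b, "from"]; t <- g$bonds[b, "to"]; o <- g$bonds[b, "order"]
      adj[[f]] <- c(adj[[f]], t); bond_order[[f]] <- c(bond_order[[f]], o)
      adj[[t]] <- c(adj[[t]], f); bond_order[[t]] <- c(bond_order[[t]], o)
    }
  }

  # Prune non-ring leaves repeatedly; what survives is rings plus linkers.
  keep <- rep(TRUE, g$n)
  repeat {
    deg <- vapply(seq_len(g$n), function(i) {
      if (!keep[i]) 0L else sum(keep[adj[[i]]])
    }, 0L)
    drop <- keep & !g$in_ring & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # Retain atoms multiply bonded to the framework (exocyclic =O, =N, =S).
  repeat {
    add <- FALSE
    for (i in seq_len(g$n)) {
      if (keep[i]) next
      nb <- adj[[i]]; bo <- bond_order[[i]]
      if (any(keep[nb] & bo >= 2L)) { keep[i] <- TRUE; add <- TRUE }
    }
    if (!add) break
  }

  # Delete side-chain atoms (descending index keeps indices valid) after
  # crediting severed single bonds to the kept atoms' implicit hydrogens.
  get_atom <- ob_fn("OBMol_GetAtom")
  for (i in seq_len(g$n)) {
    if (!keep[i]) next
    severed <- sum(bond_order[[i]][!keep[adj[[i]]]])
    if (severed > 0) {
      a <- get_atom(mol, i)
      h <- ob_fn("OBAtom_GetImplicitHCount")(a)
      ob_fn("OBAtom_SetImplicitHCount")(a, as.integer(h + severed))
    }
  }
  for (i in rev(seq_len(g$n))) {
    if (!keep[i]) ob_fn("OBMol_DeleteAtom")(mol, get_atom(mol, i))
  }
  mol_cansmi(mol)
}

#' Scaffold census of a curated dataset
#'
#' Maps every compound to its Murcko scaffold and tabulates per-scaffold
#' active/inactive counts, sorted by total membership (largest first).
#'
#' @param records data.frame with `smiles_std` and `label`.
#' @return a `scaffold_census`: data.frame with columns `scaffold`,
#'   `n_active`, `n_inactive`, `n_total`.
#' @export
scaffold_census <- function(records) {
  stopifnot(all(c("smiles_std", "label") %in% names(records)))
  scaf <- murcko_scaffold(records$smiles_std)
  df <- data.frame(scaffold = scaf, label = records$label,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(n_active = label == "active",
                                n_inactive = label == "inactive") ~ scaffold,
                          data = df, FUN = sum)
  agg$n_total <- agg$n_active + agg$n_inactive
  # unlabeled records still occupy a scaffold slot
  tot <- table(df$scaffold)
  agg$n_total <- as.integer(tot[agg$scaffold])
  agg <- agg[order(-agg$n_total, agg$scaffold, method = "radix"), ]
  rownames(agg) <- NULL
  class(agg) <- c("scaffold_census", class(agg))
  agg
}

#' @export
print.scaffold_census <- function(x, n = 10, ...) {
  cat(sprintf("scaffold census: %d scaffolds, %d compounds\n",
              nrow(x), sum(x$n_total)))
  print.data.frame(utils::head(x, n))
  invisible(x)
}
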