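# Low-level chemistry backend on OpenBabel, accessed through the ChemmineOB
# SWIG bindings (per-molecule work) and the obabel CLI (batch fingerprints).

.ob <- new.env(parent = emptyenv())

ob_fn <- function(name) {
  f <- .ob$fns[[name]]
  if (is.null(f)) {
    f <- get(name, envir = asNamespace("ChemmineOB"))
    if (is.null(.ob$fns)) .ob$fns <- list()
    .ob$fns[[name]] <- f
  }
  f
}

ob_quiet <- function() {
  # OpenBabel logs parse failures to stderr; keep only critical messages.
  if (isTRUE(.ob$quiet)) return(invisible())
  try({
    log <- ob_fn("obErrorLog_get")()
    ob_fn("OBMessageHandler_SetOutputLevel")(log, 0L)
  }, silent = TRUE)
  .ob$quiet <- TRUE
  invisible()
}

ob_conv <- function() {
  if (is.null(.ob$conv)) {
    conv <- ob_fn("OBConversion")()
    ob_fn("OBConversion_SetInFormat")(conv, "smi")
    ob_fn("OBConversion_SetOutFormat")(conv, "can")
    .ob$conv <- conv
  }
  .ob$conv
}

#' Parse a single SMILES string into an OpenBabel molecule
#'
#' @param smiles character scalar.
#' @return an external pointer to an OBMol, or `NULL` when unparseable.
#' @keywords internal
parse_mol <- function(smiles) {
  ob_quiet()
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(NULL)
  }
  mol <- ob_fn("OBMol")()
  ok <- ob_fn("OBConversion_ReadString")(ob_conv(), mol, smiles)
  if (!isTRUE(ok) || ob_fn("OBMol_NumAtoms")(mol) == 0L) NULL else mol
}

parse_mols <- function(smiles) lapply(smiles, parse_mol)

#' Canonical SMILES of an OBMol
#' @keywords internal
mol_cansmi <- function(mol) {
  out <- ob_fn("OBConversion_WriteString")(ob_conv(), mol)
  sub("[ \t\n].*$", "", out)
}

cansmi <- function(smiles) {
  mol <- parse_mol(smiles)
  if (is.null(mol)) NA_character_ else mol_cansmi(mol)
}

# ---- descriptors ------------------------------------------------------------

ob_descriptor <- function(name) {
  if (is.null(.ob$desc)) .ob$desc <- list()
  d <- .ob$desc[[name]]
  if (is.null(d)) {
    d <- ob_fn("OBDescriptor_FindType")(name)
    if (is.null(d)) stop("OpenBabel descriptor not available: ", name)
    .ob$desc[[name]] <- d
  }
  d
}

#' Predict a named OpenBabel descriptor for a list of molecules
#' @keywords internal
mol_descriptor <- function(mols, name) {
  if (identical(name, "rotors")) {
    return(vapply(mols, function(m) as.numeric(ob_fn("OBMol_NumRotors")(m)), 0))
  }
  d <- ob_descriptor(name)
  pred <- ob_fn("OBDescriptor_Predict")
  vapply(mols, function(m) as.numeric(pred(d, m)), 0)
}

mol_weight <- function(mols) {
  vapply(mols, function(m) ob_fn("OBMol_GetMolWt")(m), 0)
}

# ---- SMARTS -----------------------------------------------------------------

ob_smarts <- function(pattern) {
  if (is.null(.ob$smarts)) .ob$smarts <- list()
  sp <- .ob$smarts[[pattern]]
  if (is.null(sp)) {
    sp <- ob_fn("OBSmartsPattern")()
    if (!ob_fn("OBSmartsPattern_Init")(sp, pattern)) {
      stop("invalid SMARTS pattern: ", pattern)
    }
    .ob$smarts[[pattern]] <- sp
  }
  sp
}

#' Count unique SMARTS matches per molecule
#'
#' @param mols list of OBMol pointers.
#' @param pattern SMARTS string (compiled once and cached).
#' @return integer vector of unique match counts.
#' @keywords internal
smarts_count <- function(mols, pattern) {
  sp <- ob_smarts(pattern)
  match_fn <- ob_fn("OBSmartsPattern_Match")
  umap_fn <- ob_fn("OBSmartsPattern_GetUMapList")
  vapply(mols, function(m) {
    match_fn(sp, m)
    length(umap_fn(sp))
  }, 0L)
}

smarts_has <- function(mols, pattern) smarts_count(mols, pattern) > 0L

# ---- molecular graph --------------------------------------------------------

#' Extract the heavy-atom graph of a molecule
#'
#' Atom fields are indexed 1..n in OpenBabel order; bonds are kekulized
#' orders as stored by the SMILES reader.
#' @keywords internal
mol_graph <- function(mol) {
  n <- ob_fn("OBMol_NumAtoms")(mol)
  get_atom <- ob_fn("OBMol_GetAtom")
  z <- integer(n); arom <- logical(n); ring <- logical(n)
  hyb <- integer(n); chg <- integer(n); imph <- integer(n)
  for (i in seq_len(n)) {
    a <- get_atom(mol, i)
    z[i] <- ob_fn("OBAtom_GetAtomicNum")(a)
    arom[i] <- ob_fn("OBAtom_IsAromatic")(a)
    ring[i] <- ob_fn("OBAtom_IsInRing")(a)
    hyb[i] <- ob_fn("OBAtom_GetHyb")(a)
    chg[i] <- ob_fn("OBAtom_GetFormalCharge")(a)
    imph[i] <- ob_fn("OBAtom_GetImplicitHCount")(a)
  }
  nb <- ob_fn("OBMol_NumBonds")(mol)
  get_bond <- ob_fn("OBMol_GetBond")
  from <- integer(nb); to <- integer(nb); order <- integer(nb)
  if (nb > 0) {
    for (i in seq_len(nb)) {
      b <- get_bond(mol, i - 1L)
      from[i] <- ob_fn("OBBond_GetBeginAtomIdx")(b)
      to[i] <- ob_fn("OBBond_GetEndAtomIdx")(b)
      order[i] <- ob_fn("OBBond_GetBondOrder")(b)
    }
  }
  list(n = n, z = z, aromatic = arom, in_ring = ring, hyb = hyb,
       charge = chg, implicit_h = imph,
       bonds = cbind(from = from, to = to, order = order))
}

# Chemical element symbols by atomic number, for the elements we ever meet.
.element_symbols <- c(
  "1" = "H", "5" = "B", "6" = "C", "7" = "N", "8" = "O", "9" = "F",
  "14" = "Si", "15" = "P", "16" = "S", "17" = "Cl", "34" = "Se",
  "35" = "Br", "53" = "I", "11" = "Na", "19" = "K", "50" = "Sn",
  "80" = "Hg", "33" = "As", "3" = "Li", "12" = "Mg", "20" = "Ca",
  "26" = "Fe", "30" = "Zn"
)

mol_atomic_numbers <- function(mol) {
  n <- ob_fn("OBMol_NumAtoms")(mol)
  get_atom <- ob_fn("OBMol_GetAtom")
  vapply(seq_len(n), function(i) {
    ob_fn("OBAtom_GetAtomicNum")(get_atom(mol, i))
  }, 0L)
}

# ---- batch ECFP4 fingerprints via the obabel CLI ---------------------------

.hex_nibble <- local({
  tbl <- matrix(0L, 16, 4)
  for (v in 0:15) tbl[v + 1L, ] <- as.integer(bitwAnd(bitwShiftR(v, 3:0), 1L))
  rownames(tbl) <- c(as.character(0:9), letters[1:6])
  tbl
})

#' Batch ECFP fingerprints through obabel's FPS writer
#'
#' Returns the raw 4096-bit OpenBabel ECFP4 matrix; callers fold it.
#' Unparseable SMILES raise an error naming the offending inputs.
#' @keywords internal
ecfp4_raw <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    return(matrix(0L, 0L, 4096L))
  }
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) stop("obabel executable not found on PATH")
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".fps")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), infile)
  system2(obabel, c(infile, "-ofps", "-xfECFP4", "-O", outfile, "-e"),
          stdout = FALSE, stderr = FALSE)
  lines <- readLines(outfile)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  hex <- tolower(vapply(parts, `[[`, "", 1L))
  idx <- as.integer(vapply(parts, `[[`, "", 2L))
  if (anyNA(idx) || length(idx) != length(smiles) ||
      !setequal(idx, seq_along(smiles))) {
    bad <- setdiff(seq_along(smiles), idx)
    stop("fingerprinting failed for SMILES: ",
         paste(utils::head(smiles[bad], 5L), collapse = ", "))
  }
  nhex <- nchar(hex[1L])
  chars <- matrix(unlist(strsplit(hex, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(hex), byrow = TRUE)
  bits <- matrix(0L, length(hex), nhex * 4L)
  for (j in seq_len(nhex)) {
    bits[, (4L * (j - 1L) + 1L):(4L * j)] <- .hex_nibble[chars[, j], , drop = FALSE]
  }
  out <- matrix(0L, length(smiles), ncol(bits))
  out[idx, ] <- bits
  out
}
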