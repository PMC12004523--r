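# Dataset curation: standardize, label, filter, deduplicate, with a
# stage-by-stage audit report.

#' Curate a raw compound table into a clean labeled dataset
#'
#' Applies the full preprocessing cascade: structure standardization,
#' activity labeling (potency or score semantics chosen by `source`),
#' element/molecular-weight admission, removal of score-excluded records,
#' and label-aware deduplication on canonical SMILES. Records from a
#' `library` source are kept unlabeled.
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `source` (one of `"potency_source"`, `"score_source"`, `"library"`)
#'   and `activity_value` (pChEMBL-style numeric for potency sources,
#'   integer score 0-100 for score sources, ignored for libraries).
#' @param mw_min,mw_max inclusive molecular-weight bounds in Da.
#' @return a list of class `curation_result` with elements `data` (the
#'   curated data.frame, adding `smiles_std` and `label`) and `report`
#'   (a `curation_report`).
#' @export
curate_compounds <- function(records, mw_min = 250, mw_max = 900) {
  required <- c("compound_id", "smiles", "source")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("records is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"activity_value" %in% names(records)) records$activity_value <- NA_real_
  bad_src <- setdiff(unique(records$source),
                     c("potency_source", "score_source", "library"))
  if (length(bad_src) > 0) stop("unknown source tag: ", paste(bad_src, collapse = ", "))
  if (anyDuplicated(records$compound_id)) {
    stop("compound_id values must be unique within an input table")
  }

  stages <- list()
  reasons <- list()
  n0 <- nrow(records)

  # stage 1: standardization
  std <- standardize_structure(records$smiles)
  records$smiles_std <- std$smiles_std
  keep <- !is.na(records$smiles_std)
  reasons$standardize <- table_reasons(std$reason[!keep])
  stages$standardize <- c(n_in = n0, n_out = sum(keep))
  records <- records[keep, , drop = FALSE]

  # stage 2: element / molecular weight admission
  ew <- element_weight_filter(records$smiles_std, mw_min = mw_min, mw_max = mw_max)
  keep <- ew$pass
  reasons$element_weight <- table_reasons(ew$reason[!keep])
  stages$element_weight <- c(n_in = nrow(records), n_out = sum(keep))
  records <- records[keep, , drop = FALSE]

  # stage 3: labeling (score-excluded records dropped here)
  records$label <- rep("unlabeled", nrow(records))
  pot <- records$source == "potency_source"
  sco <- records$source == "score_source"
  if (any(pot)) records$label[pot] <- label_by_potency(records$activity_value[pot])
  if (any(sco)) records$label[sco] <- label_by_score(records$activity_value[sco])
  keep <- records$label != "excluded"
  reasons$labeling <- table_reasons(rep("score-excluded-band", sum(!keep)))
  stages$labeling <- c(n_in = nrow(records), n_out = sum(keep))
  records <- records[keep, , drop = FALSE]

  # stage 4: deduplication on canonical SMILES
  dedup <- deduplicate_records(records)
  reasons$deduplicate <- dedup$reasons
  stages$deduplicate <- c(n_in = nrow(records), n_out = nrow(dedup$data))
  records <- dedup$data

  rownames(records) <- NULL
  report <- new_curation_report(stages, reasons)
  structure(list(data = records, report = report), class = "curation_result")
}

table_reasons <- function(x) {
  if (length(x) == 0) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' Deduplicate curated records on canonical SMILES
#'
#' Groups records by `smiles_std`. Groups whose members agree on the label
#' keep one representative (first by `compound_id` sort order); groups with
#' conflicting labels are removed entirely.
#'
#' @param records data.frame with `smiles_std`, `label`, `compound_id`.
#' @return list with `data` (deduplicated data.frame, ordered by
#'   `compound_id`) and `reasons` (named integer vector of removal counts).
#' @export
deduplicate_records <- function(records) {
  stopifnot(all(c("smiles_std", "label", "compound_id") %in% names(records)))
  if (nrow(records) == 0) {
    return(list(data = records, reasons = integer(0)))
  }
  ord <- order(records$compound_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  groups <- split(seq_len(nrow(records)), records$smiles_std)
  keep_idx <- integer(0)
  n_dup <- 0L
  n_conflict <- 0L
  for (g in groups) {
    labels <- unique(records$label[g])
    if (length(labels) == 1L) {
      keep_idx <- c(keep_idx, g[1L])
      n_dup <- n_dup + length(g) - 1L
    } else {
      n_conflict <- n_conflict + length(g)
    }
  }
  out <- records[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  reasons <- c(`duplicate-same-label` = n_dup,
               `conflicting-labels` = n_conflict)
  list(data = out, reasons = reasons[reasons > 0])
}

#' Cross-source overlap of curated datasets
#'
#' Counts canonical SMILES shared between two curated datasets, split by
#' label agreement, in the style of a Venn-diagram comparison. Compounds
#' present in both sources with disagreeing labels are reported separately
#' for manual review (conflicts across sources are not auto-resolved).
#'
#' @param set_a,set_b curated data.frames with `smiles_std` and `label`.
#' @return list with `shared_active`, `shared_inactive`,
#'   `conflicting` (counts) and `conflicting_smiles`.
#' @export
cross_source_overlap <- function(set_a, set_b) {
  common <- intersect(set_a$smiles_std, set_b$smiles_std)
  la <- set_a$label[match(common, set_a$smiles_std)]
  lb <- set_b$label[match(common, set_b$smiles_std)]
  agree <- la == lb
  list(shared_active = sum(agree & la == "active"),
       shared_inactive = sum(agree & la == "inactive"),
       conflicting = sum(!agree),
       conflicting_smiles = common[!agree])
}

# ---- curation report --------------------------------------------------------

new_curation_report <- function(stages, reasons) {
  df <- data.frame(stage = names(stages),
                   n_in = vapply(stages, `[[`, 0, "n_in"),
                   n_out = vapply(stages, `[[`, 0, "n_out"),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(stages = df, rejection_reasons = reasons),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  for (i in seq_len(nrow(x$stages))) {
    st <- x$stages[i, ]
    cat(sprintf("  %-16s %6d -> %6d\n", st$stage, st$n_in, st$n_out))
    rr <- x$rejection_reasons[[st$stage]]
    if (length(rr) > 0) {
      for (nm in names(rr)) cat(sprintf("      %-24s %d\n", nm, rr[[nm]]))
    }
  }
  invisible(x)
}

#' Convert a curation report to a plain list (for JSON serialization)
#' @param x a `curation_report`.
#' @export
as.list.curation_report <- function(x, ...) {
  list(stages = x$stages, rejection_reasons = x$rejection_reasons)
}
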