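## Consensus computational alanine scanning.
##
## Per-residue binding free-energy changes on alanine substitution (ddG,
## kcal/mol; positive = destabilizing) predicted by several tools on several
## docking models are averaged first over models (to account for protein
## flexibility) and then over predictors (to obtain a consensus), and the
## consensus ranks interface hotspots.

#' Read a long-format ddG table
#'
#' Columns: `chain`, `resnum`, `restype`, `predictor`, `model_id`, `ddg`.
#' @param path CSV path.
#' @return data.frame of ddG entries.
#' @export
read_ddg_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "resnum", "restype", "predictor", "model_id", "ddg")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("ddG table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(is.finite(tab$ddg))) stop("non-finite ddG values")
  tab
}

#' Consensus hotspot ranking from ddG predictions
#'
#' For each (residue, predictor), the mean ddG over models is taken; the
#' consensus is the mean of those per-predictor means. Residues covered by
#' fewer than `min_coverage` of the predictors are excluded with a warning.
#' Ranking is by descending consensus, ties broken by residue number.
#'
#' @param entries ddG entries ([read_ddg_table()] format).
#' @param min_coverage Minimum fraction of predictors that must report a
#'   residue (default 0.5).
#' @param grand_mean If `TRUE`, average all entries of a residue directly
#'   (unweighted grand mean) instead of models-then-predictors; offered for
#'   sensitivity checks.
#' @return data.frame of class `hotspot_ranking`: `residue`, `chain`,
#'   `resnum`, `restype`, `consensus_ddg`, `rank`, plus per-predictor mean
#'   columns.
#' @export
consensus_rank <- function(entries, min_coverage = 0.5, grand_mean = FALSE) {
  entries$residue <- paste0(entries$chain, ":", entries$resnum)
  predictors <- sort(unique(entries$predictor))
  ## mean over models per (residue, predictor)
  pm <- aggregate(ddg ~ residue + predictor, data = entries, FUN = mean)
  cov <- table(pm$residue)
  low <- names(cov)[cov < min_coverage * length(predictors)]
  if (length(low) > 0) {
    warning("residue(s) covered by fewer than ",
            round(100 * min_coverage), "% of predictors excluded: ",
            paste(low, collapse = ", "))
    pm <- pm[!(pm$residue %in% low), , drop = FALSE]
    entries <- entries[!(entries$residue %in% low), , drop = FALSE]
  }
  if (nrow(pm) == 0) stop("no residue passes the predictor-coverage rule")
  cons <- if (grand_mean) {
    aggregate(ddg ~ residue, data = entries, FUN = mean)
  } else {
    aggregate(ddg ~ residue, data = pm, FUN = mean)
  }
  names(cons)[2] <- "consensus_ddg"
  meta <- entries[!duplicated(entries$residue),
                  c("residue", "chain", "resnum", "restype")]
  out <- merge(cons, meta, by = "residue")
  wide <- do.call(rbind, lapply(split(pm, pm$residue), function(g)
    data.frame(residue = g$residue[1],
               t(setNames(g$ddg, paste0("mean_", g$predictor))),
               check.names = FALSE)))
  out <- merge(out, wide, by = "residue", all.x = TRUE)
  out <- out[order(-out$consensus_ddg, out$resnum), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("hotspot_ranking", "data.frame")
  out
}

#' Select top-ranked hotspots
#'
#' The `top_k` best-ranked residues plus any manual additions (e.g. a highly
#' ranked hydrophobic residue selected on structural grounds), deduplicated
#' and ordered by rank.
#'
#' @param ranking A [consensus_rank()] result.
#' @param top_k Number of top-ranked residues (default 7).
#' @param manual_add Character vector of `"chain:resnum"` keys to add.
#' @return Character vector of residue keys.
#' @export
select_hotspots <- function(ranking, top_k = 7, manual_add = character()) {
  if (top_k > nrow(ranking)) stop("top_k exceeds the number of ranked residues")
  missing <- setdiff(manual_add, ranking$residue)
  if (length(missing) > 0)
    stop("manual residue(s) absent from ranking: ",
         paste(missing, collapse = ", "))
  keep <- ranking$residue %in%
    c(ranking$residue[seq_len(top_k)], manual_add)
  ranking$residue[keep]
}

#' Intermolecular contacts of hotspot residues
#'
#' For each hotspot, the partner-chain residues with any heavy atom within
#' `cutoff`, reported per model and as the union across models.
#'
#' @param models List of `complex_model`s (e.g. the top 4 of the best
#'   cluster).
#' @param hotspots Character vector of `"chain:resno"` keys on the ligand.
#' @param cutoff Heavy-atom contact distance (default 5.5 Angstrom).
#' @return List per hotspot with `union` (partner residue keys) and
#'   `per_model` (named list of keys).
#' @export
hotspot_contacts <- function(models, hotspots, cutoff = 5.5) {
  out <- lapply(hotspots, function(h) {
    per_model <- lapply(models, function(m) {
      s <- m$structure
      k <- residue_key(s)
      if (!h %in% k) stop("hotspot '", h, "' not found in model '",
                          m$model_id, "'")
      hs <- new_structure(s[k == h, , drop = FALSE])
      partner_chains <- if (sub(":.*", "", h) %in% m$ligand_chain)
        m$receptor_chains else m$ligand_chain
      partner <- structure_chains(s, partner_chains)
      cc <- contacts(hs, partner, cutoff = cutoff, atom_class = "heavy")
      sort(unique(cc$res_b))
    })
    names(per_model) <- vapply(models, `[[`, "", "model_id")
    list(union = sort(unique(unlist(per_model))), per_model = per_model)
  })
  names(out) <- hotspots
  out
}

#' Overlap between actin-binding hotspots and AID-binding residues
#'
#' Set intersection between the predicted actin-binding hotspots and the
#' residues critical for association with the alpha-subunit AID helix; an
#' empty overlap means the two binding functions use distinct surfaces.
#'
#' @param hotspots,aid_critical Character vectors of residue keys.
#' @return Character vector (possibly empty) of shared residues.
#' @export
aid_overlap <- function(hotspots, aid_critical) {
  sort(intersect(hotspots, aid_critical))
}
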