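## Evaluation of protein-protein docking ensembles: HADDOCK-style scoring,
## CAPRI RMSD metrics (global, interface, ligand and interface-ligand RMSD),
## neighbour-count clustering, restraint-violation checks, contact-frequency
## interface maps, ensemble averaging and cross-complex comparison.
##
## Energy terms are inputs read from an ensemble manifest; force-field
## evaluation is out of scope.

#' Construct a docking complex model
#'
#' @param structure A `Structure` holding receptor and ligand chains.
#' @param receptor_chains,ligand_chain Chain designations (disjoint).
#' @param energies Optional named numeric vector with elements `E_vdw`,
#'   `E_elec`, `E_desol`, `E_air`.
#' @param model_id Model identifier.
#' @return List of class `complex_model`.
#' @export
complex_model <- function(structure, receptor_chains, ligand_chain,
                          energies = NULL, model_id = "model") {
  if (length(intersect(receptor_chains, ligand_chain)) > 0)
    stop("receptor and ligand chain sets must be disjoint")
  if (!all(c(receptor_chains, ligand_chain) %in% structure$chain))
    stop("designated chains absent from structure")
  structure(list(structure = structure, receptor_chains = receptor_chains,
                 ligand_chain = ligand_chain, energies = energies,
                 model_id = model_id),
            class = "complex_model")
}

#' Bundle complex models into an ensemble
#'
#' @param models List of [complex_model()]s sharing chain topology and
#'   residue numbering.
#' @return List of class `ensemble`.
#' @export
ensemble <- function(models) {
  if (length(models) < 1) stop("an ensemble needs at least one model")
  key0 <- with(models[[1]]$structure, paste(chain, resno, elety))
  for (m in models[-1]) {
    if (!identical(with(m$structure, paste(chain, resno, elety)), key0))
      stop("model '", m$model_id, "' does not share the ensemble topology")
  }
  structure(list(models = models,
                 receptor_chains = models[[1]]$receptor_chains,
                 ligand_chain = models[[1]]$ligand_chain),
            class = "ensemble")
}

#' Read a docking ensemble from a manifest
#'
#' The manifest is a CSV with columns `model_id`, `pdb_path` and optionally
#' `E_vdw`, `E_elec`, `E_desol`, `E_air`. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param receptor_chains,ligand_chain Chain designations.
#' @return An [ensemble()].
#' @export
read_ensemble <- function(path, receptor_chains, ligand_chain) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  eterms <- c("E_vdw", "E_elec", "E_desol", "E_air")
  models <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$pdb_path[i]
    if (!file.exists(p)) p <- file.path(base, man$pdb_path[i])
    en <- if (all(eterms %in% names(man)))
      setNames(as.numeric(man[i, eterms]), eterms) else NULL
    complex_model(read_pdb(p), receptor_chains, ligand_chain,
                  energies = en, model_id = as.character(man$model_id[i]))
  })
  ensemble(models)
}

#' HADDOCK score of a docking model
#'
#' Weighted sum of the van der Waals, electrostatic, desolvation and
#' restraint-energy terms; lower is better.
#'
#' @param m A `complex_model` with all four energy terms.
#' @param weights Named weights (defaults 1.0, 0.2, 1.0, 0.1).
#' @return Numeric score.
#' @export
haddock_score <- function(m, weights = c(E_vdw = 1.0, E_elec = 0.2,
                                         E_desol = 1.0, E_air = 0.1)) {
  terms <- names(weights)
  missing <- terms[!(terms %in% names(m$energies))]
  if (is.null(m$energies) || length(missing) > 0)
    stop("model '", m$model_id, "' lacks energy term(s): ",
         paste(if (is.null(m$energies)) terms else missing, collapse = ", "))
  sum(weights * m$energies[terms])
}

## paired coordinates of selected atoms, matched by (chain, resno, elety)
paired_coords <- function(a, b, chains = NULL, atom_class = "calpha",
                          residues = NULL) {
  sel <- function(s) {
    s <- select_atoms(s, atom_class)
    if (!is.null(chains)) s <- s[s$chain %in% chains, , drop = FALSE]
    if (!is.null(residues))
      s <- s[residue_key(s) %in% residues, , drop = FALSE]
    s
  }
  sa <- sel(a); sb <- sel(b)
  ka <- with(sa, paste(chain, resno, elety))
  kb <- with(sb, paste(chain, resno, elety))
  common <- intersect(ka, kb)
  if (length(common) == 0) stop("no matching atoms between structures")
  list(a = coord_matrix(sa)[match(common, ka), , drop = FALSE],
       b = coord_matrix(sb)[match(common, kb), , drop = FALSE])
}

## reference-defined interface residues at a heavy-atom cutoff
interface_residues <- function(m, cutoff = 10) {
  rec <- structure_chains(m$structure, m$receptor_chains)
  lig <- structure_chains(m$structure, m$ligand_chain)
  cc <- contacts(rec, lig, cutoff = cutoff, atom_class = "heavy")
  unique(c(cc$res_a, cc$res_b))
}

#' CAPRI-style RMSD metrics of a model against a reference
#'
#' * `global_rmsd`: Calpha RMSD over all residues of both chains after
#'   fitting on those same atoms.
#' * `i_rmsd`: backbone RMSD over the reference's interface residues (any
#'   heavy atom of one chain within `interface_cutoff` of the other), after
#'   fitting on those interfacial atoms.
#' * `l_rmsd`: backbone RMSD over the ligand after fitting on the receptor
#'   backbone.
#'
#' @param m,reference `complex_model`s sharing residue numbering.
#' @param interface_cutoff Heavy-atom distance defining the interface
#'   (Angstrom).
#' @return Named numeric vector `global_rmsd`, `i_rmsd`, `l_rmsd`.
#' @export
rmsd_metrics <- function(m, reference, interface_cutoff = 10) {
  all_chains <- c(reference$receptor_chains, reference$ligand_chain)
  g <- paired_coords(m$structure, reference$structure, chains = all_chains,
                     atom_class = "calpha")
  global_rmsd <- superpose(g$a, g$b)$rmsd
  iface <- interface_residues(reference, cutoff = interface_cutoff)
  if (length(iface) == 0)
    stop("empty interface at cutoff ", interface_cutoff, " Angstrom")
  i <- paired_coords(m$structure, reference$structure,
                     atom_class = "backbone", residues = iface)
  i_rmsd <- superpose(i$a, i$b)$rmsd
  r <- paired_coords(m$structure, reference$structure,
                     chains = reference$receptor_chains,
                     atom_class = "backbone")
  fit <- superpose(r$a, r$b)
  l <- paired_coords(m$structure, reference$structure,
                     chains = reference$ligand_chain,
                     atom_class = "backbone")
  l_rmsd <- coord_rmsd(apply_transform(l$a, fit), l$b, fit = FALSE)
  c(global_rmsd = global_rmsd, i_rmsd = i_rmsd, l_rmsd = l_rmsd)
}

#' Ensemble-wide flexible interface
#'
#' Union over all models of the residues making inter-chain contacts within
#' `cutoff` (heavy atoms).
#'
#' @param e An `ensemble`.
#' @param cutoff Contact distance (Angstrom).
#' @return Character vector of `"chain:resno"` residue keys.
#' @export
flexible_interface <- function(e, cutoff = 5) {
  sort(unique(unlist(lapply(e$models, function(m)
    interface_residues(m, cutoff = cutoff)))))
}

## interface-ligand RMSD between two models given a flexible interface:
## fit on receptor-side interface backbone, measure on ligand-side interface
## backbone.
il_rmsd <- function(a, b, iface) {
  rec <- paired_coords(a$structure, b$structure,
                       chains = a$receptor_chains, atom_class = "backbone",
                       residues = iface)
  fit <- superpose(rec$a, rec$b)
  lig <- paired_coords(a$structure, b$structure, chains = a$ligand_chain,
                       atom_class = "backbone", residues = iface)
  coord_rmsd(apply_transform(lig$a, fit), lig$b, fit = FALSE)
}

#' Pairwise interface-ligand RMSD matrix
#'
#' @param e An `ensemble`.
#' @param iface Flexible interface residues; defaults to
#'   [flexible_interface()] at 5 Angstrom.
#' @return Symmetric numeric matrix.
#' @export
il_rmsd_matrix <- function(e, iface = flexible_interface(e)) {
  if (length(iface) == 0)
    stop("empty flexible interface; increase the contact cutoff")
  n <- length(e$models)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- il_rmsd(e$models[[i]], e$models[[j]], iface)
    }
  }
  dimnames(M) <- list(vapply(e$models, `[[`, "", "model_id"),
                      vapply(e$models, `[[`, "", "model_id"))
  M
}

#' Cluster a docking ensemble by interface-ligand RMSD
#'
#' Iteratively selects the model with the most neighbours within `cutoff`
#' (ties broken by lower model index), forms a cluster of the centre plus its
#' neighbours when the cluster reaches `min_neighbors` members in total,
#' removes them, and repeats. Clusters are ranked by the average HADDOCK
#' score of their four best-scoring members (when energies are present).
#'
#' @param e An `ensemble`.
#' @param cutoff i-l-RMSD cutoff in Angstrom (default 7.5).
#' @param min_neighbors Minimum cluster size in members (default 4).
#' @param iface_cutoff Contact cutoff defining the flexible interface
#'   (Angstrom); pseudo-atom models without side chains need an inflated
#'   value.
#' @param dmat Optional precomputed [il_rmsd_matrix()].
#' @return List of class `cluster_result`: `clusters` (list of model-id
#'   vectors, ranked), `centers`, `scores` (average of the 4 best member
#'   scores, `NA` without energies), `unclustered`.
#' @export
cluster_ensemble <- function(e, cutoff = 7.5, min_neighbors = 4,
                             iface_cutoff = 5, dmat = NULL) {
  ids <- vapply(e$models, `[[`, "", "model_id")
  if (is.null(dmat))
    dmat <- il_rmsd_matrix(e, iface = flexible_interface(e, iface_cutoff))
  n <- length(ids)
  remaining <- seq_len(n)
  clusters <- list(); centers <- integer()
  while (length(remaining) > 0) {
    nb <- lapply(remaining, function(i)
      remaining[dmat[i, remaining] <= cutoff & remaining != i])
    counts <- lengths(nb)
    best <- which.max(counts)                 # ties -> lower model index
    if (counts[best] + 1 < min_neighbors) break
    members <- sort(c(remaining[best], nb[[best]]))
    clusters[[length(clusters) + 1]] <- members
    centers <- c(centers, remaining[best])
    remaining <- setdiff(remaining, members)
  }
  has_energy <- all(vapply(e$models, function(m)
    !is.null(m$energies), logical(1)))
  scores <- rep(NA_real_, length(clusters))
  if (has_energy && length(clusters) > 0) {
    all_scores <- vapply(e$models, haddock_score, numeric(1))
    scores <- vapply(clusters, function(mem)
      mean(sort(all_scores[mem])[seq_len(min(4, length(mem)))]), numeric(1))
    ord <- order(scores)
    clusters <- clusters[ord]; centers <- centers[ord]; scores <- scores[ord]
  } else if (!has_energy && length(clusters) > 0) {
    warning("energies absent: clusters returned unranked")
  }
  structure(list(clusters = lapply(clusters, function(i) ids[i]),
                 centers = ids[centers], scores = scores,
                 unclustered = ids[remaining]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%d cluster(s), %d unclustered model(s)\n",
              length(x$clusters), length(x$unclustered)))
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d models (center %s, score %s)\n", i,
                length(x$clusters[[i]]), x$centers[i],
                format(x$scores[i], digits = 4)))
  invisible(x)
}

#' Check ensemble models against distance restraints
#'
#' Per model and restraint, the minimum Calpha-Calpha distance over the
#' restraint's ambiguity set is classified as satisfied (<= `satisfied_max`),
#' tolerated (up to `tolerated_max`) or violated.
#'
#' @param e An `ensemble`.
#' @param restraints Restraint table ([distance_restraints()]); anchors refer
#'   to chains of the models.
#' @param satisfied_max,tolerated_max Distance bands in Angstrom (30/35).
#' @return List with `distances` (models x restraints matrix) and `fractions`
#'   (per restraint: satisfied/tolerated/violated, summing to 1).
#' @export
restraint_check <- function(e, restraints, satisfied_max = 30,
                            tolerated_max = 35) {
  n <- length(e$models)
  D <- matrix(NA_real_, n, nrow(restraints),
              dimnames = list(vapply(e$models, `[[`, "", "model_id"),
                              restraints$id))
  for (i in seq_len(n)) {
    s <- e$models[[i]]$structure
    for (r in seq_len(nrow(restraints))) {
      fx <- anchor_coords(s, strsplit(restraints$fixed[r], "|",
                                      fixed = TRUE)[[1]])
      sc <- anchor_coords(s, restraints$scan[r])
      D[i, r] <- sqrt(min(rowSums(sweep(fx, 2, sc[1, ])^2)))
    }
  }
  frac <- t(apply(D, 2, function(d) {
    c(satisfied = mean(d <= satisfied_max),
      tolerated = mean(d > satisfied_max & d <= tolerated_max),
      violated = mean(d > tolerated_max))
  }))
  list(distances = D, fractions = frac)
}

#' Residue contact frequency across an ensemble
#'
#' Fraction of models in which each residue makes an inter-chain heavy-atom
#' contact within `cutoff`.
#'
#' @param e An `ensemble`.
#' @param cutoff Contact distance (Angstrom).
#' @return data.frame with `residue` and `frequency` in `[0, 1]`, covering
#'   every residue observed in contact in at least one model.
#' @export
contact_frequency <- function(e, cutoff = 5) {
  per_model <- lapply(e$models, function(m) interface_residues(m, cutoff))
  all_res <- sort(unique(unlist(per_model)))
  freq <- vapply(all_res, function(r)
    mean(vapply(per_model, function(s) r %in% s, logical(1))), numeric(1))
  data.frame(residue = all_res, frequency = unname(freq),
             stringsAsFactors = FALSE)
}

#' Average structure of a set of models
#'
#' Superposes every model onto the first (receptor backbone fit) and averages
#' coordinates atom-wise.
#'
#' @param models List of `complex_model`s with shared topology.
#' @return A `Structure` with mean coordinates.
#' @export
average_structure <- function(models) {
  if (length(models) < 2) stop("need at least 2 models to average")
  ref <- models[[1]]
  key0 <- with(ref$structure, paste(chain, resno, elety))
  acc <- coord_matrix(ref$structure)
  for (m in models[-1]) {
    if (!identical(with(m$structure, paste(chain, resno, elety)), key0))
      stop("model '", m$model_id, "' topology mismatch")
    r <- paired_coords(m$structure, ref$structure,
                       chains = ref$receptor_chains, atom_class = "backbone")
    fit <- superpose(r$a, r$b)
    acc <- acc + apply_transform(coord_matrix(m$structure), fit)
  }
  out <- ref$structure
  xyz <- acc / length(models)
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  new_structure(out)
}

#' Compare a complex model to a reference through a residue correspondence
#'
#' Computes l-RMSD and interface RMSD over mapped residues only, plus the
#' percent sequence identity of the mapped interface positions. Interface
#' residues of the reference lacking a mapping are excluded (with a warning
#' reporting the count).
#'
#' @param candidate,reference `complex_model`s (possibly different proteins).
#' @param residue_map data.frame with columns `candidate` and `reference`
#'   (`"chain:resno"` keys).
#' @param interface_cutoff Heavy-atom interface cutoff on the reference
#'   (Angstrom).
#' @return List with `l_rmsd`, `i_rmsd`, `interface_identity` (percent) and
#'   `n_unmapped_interface`.
#' @export
compare_to_reference <- function(candidate, reference, residue_map,
                                 interface_cutoff = 10) {
  map <- setNames(residue_map$candidate, residue_map$reference)
  pair_map_coords <- function(res_keys, chains_ref, atom_class) {
    res_keys <- res_keys[res_keys %in% names(map)]
    sr <- select_atoms(reference$structure, atom_class)
    sc <- select_atoms(candidate$structure, atom_class)
    kr <- residue_key(sr); kc <- residue_key(sc)
    A <- NULL; B <- NULL
    for (rk in res_keys) {
      ri <- which(kr == rk); ci <- which(kc == map[[rk]])
      common <- intersect(sr$elety[ri], sc$elety[ci])
      if (length(common) == 0) next
      A <- rbind(A, coord_matrix(sc)[ci[match(common, sc$elety[ci])], ,
                                     drop = FALSE])
      B <- rbind(B, coord_matrix(sr)[ri[match(common, sr$elety[ri])], ,
                                     drop = FALSE])
    }
    list(a = A, b = B)
  }
  ref_res <- unique(residue_key(reference$structure))
  rec_res <- ref_res[sub(":.*", "", ref_res) %in% reference$receptor_chains]
  lig_res <- ref_res[sub(":.*", "", ref_res) %in% reference$ligand_chain]
  rec <- pair_map_coords(rec_res, atom_class = "backbone")
  fit <- superpose(rec$a, rec$b)
  lig <- pair_map_coords(lig_res, atom_class = "backbone")
  l_rmsd <- coord_rmsd(apply_transform(lig$a, fit), lig$b, fit = FALSE)

  iface <- interface_residues(reference, cutoff = interface_cutoff)
  unmapped <- setdiff(iface, names(map))
  if (length(unmapped) > 0)
    warning(length(unmapped), " interface residue(s) lack a mapping and ",
            "were excluded")
  iface_m <- intersect(iface, names(map))
  ic <- pair_map_coords(iface_m, atom_class = "backbone")
  i_rmsd <- superpose(ic$a, ic$b)$rmsd

  rtype <- function(s, keys) {
    k <- residue_key(s$structure)
    vapply(keys, function(x) s$structure$resid[match(x, k)], character(1))
  }
  ident <- mean(rtype(reference, iface_m) ==
                  rtype(candidate, unname(map[iface_m]))) * 100
  list(l_rmsd = l_rmsd, i_rmsd = i_rmsd, interface_identity = ident,
       n_unmapped_interface = length(unmapped))
}
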