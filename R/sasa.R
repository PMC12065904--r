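## Shrake-Rupley solvent-accessible surface area and relative accessibility.
##
## Deterministic golden-spiral sphere sampling (960 points/atom by default);
## no external SASA binary is required. Relative accessibility divides the
## per-residue SASA by a configurable per-residue reference maximum
## (theoretical Gly-X-Gly maxima by default), an approximation to NACCESS-style
## relative accessibility.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
VDW_DEFAULT <- 1.80

## Deterministic quasi-uniform unit sphere points (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' @param s A `Structure` (heavy atoms; hydrogens are assumed absent).
#' @param probe_radius Solvent probe radius in Angstrom.
#' @param n_points Sphere sample points per atom; deterministic golden-spiral
#'   set, so results are reproducible for a given count.
#' @return data.frame with columns `residue` ("chain:resno"), `resid`
#'   (3-letter code) and `sasa` (Angstrom^2).
#' @export
sasa_residue <- function(s, probe_radius = 1.4, n_points = 960) {
  s <- as_structure(s)
  xyz <- coord_matrix(s)
  rad <- atom_radii(s$element) + probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  ## neighbour lists from the full distance matrix (fixtures are small)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  for (i in seq_len(n)) {
    cutoff2 <- (rad[i] + rad)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  key <- residue_key(s)
  agg <- rowsum(area, key)
  resid <- s$resid[!duplicated(key)]
  names(resid) <- key[!duplicated(key)]
  out <- data.frame(residue = rownames(agg), resid = resid[rownames(agg)],
                    sasa = agg[, 1], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Default per-residue reference maximum SASA table
#'
#' Theoretical maximum accessible surface areas (Angstrom^2) of residue X in
#' an extended Gly-X-Gly context, shipped as a plain-text data file so users
#' can substitute their own reference.
#'
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
max_sasa_reference <- function() {
  path <- system.file("extdata", "max_sasa_reference.csv",
                      package = "betactin")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  setNames(tab$max_sasa, tab$resid)
}

#' Relative solvent accessibility per residue
#'
#' Shrake-Rupley SASA per residue divided by a per-residue reference maximum,
#' expressed in percent. Values can slightly exceed 100% when a conformation
#' is more exposed than the reference context.
#'
#' @inheritParams sasa_residue
#' @param reference Named numeric vector of reference maxima (Angstrom^2) per
#'   3-letter residue code; defaults to [max_sasa_reference()].
#' @return data.frame with columns `residue`, `resid`, `sasa`,
#'   `rel_accessibility` (percent).
#' @export
relative_accessibility <- function(s, probe_radius = 1.4, n_points = 960,
                                   reference = max_sasa_reference()) {
  res <- sasa_residue(s, probe_radius = probe_radius, n_points = n_points)
  unknown <- setdiff(unique(res$resid), names(reference))
  if (length(unknown) > 0)
    stop("residue type(s) absent from reference table: ",
         paste(unknown, collapse = ", "))
  res$rel_accessibility <- 100 * res$sasa / reference[res$resid]
  res
}
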