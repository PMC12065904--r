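## Accessible-interaction-space analysis of XL-MS distance restraints.
##
## A deterministic set of quasi-uniform rotations crossed with a translation
## grid bounding the fixed chain (plus the maximum restraint bound as margin)
## enumerates rigid-body poses of the scanning chain. Non-clashing poses are
## tallied by the number of restraints they satisfy; restraints that are
## violated in almost all of the most-consistent poses are flagged as likely
## false positives and can be discarded iteratively.

#' Define Calpha-Calpha distance restraints
#'
#' @param fixed Character vector of fixed-chain anchor selections, each a
#'   `"chain:resno"` string; ambiguous alternatives (e.g. the equivalent
#'   residue on the adjacent filament subunit) are separated by `"|"`.
#' @param scan Character vector of scanning-chain anchors (`"chain:resno"`).
#' @param d_min,d_max Allowed Calpha-Calpha distance range in Angstrom
#'   (default 0-30, covering the lysine side chains, the cross-linker spacer
#'   and conformational dynamics).
#' @param id Optional restraint labels.
#' @return data.frame of restraints.
#' @export
distance_restraints <- function(fixed, scan, d_min = 0, d_max = 30,
                                id = NULL) {
  n <- length(fixed)
  if (length(scan) != n) stop("fixed and scan must have equal length")
  out <- data.frame(id = if (is.null(id)) paste0("xl", seq_len(n)) else id,
                    fixed = fixed, scan = scan,
                    d_min = rep_len(d_min, n), d_max = rep_len(d_max, n),
                    stringsAsFactors = FALSE)
  if (any(out$d_min > out$d_max)) stop("d_min must not exceed d_max")
  out
}

#' Read restraints from a CSV file
#'
#' Expected columns: `fixed` (with `"|"`-separated alternates), `scan`,
#' optional `d_min`, `d_max`, `id`.
#' @param path CSV path.
#' @return data.frame of restraints.
#' @export
read_restraints <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  distance_restraints(fixed = tab$fixed, scan = tab$scan,
                      d_min = if ("d_min" %in% names(tab)) tab$d_min else 0,
                      d_max = if ("d_max" %in% names(tab)) tab$d_max else 30,
                      id = if ("id" %in% names(tab)) tab$id else NULL)
}

#' Configure the rigid-body scan
#'
#' @param rotation_count Number of sampled rotations; the first is always the
#'   identity, the remainder are quasi-uniform random orientations drawn
#'   deterministically from `seed`. `rotation_count = 1` scans translations
#'   only.
#' @param grid_spacing Translation grid spacing in Angstrom.
#' @param clash_distance Minimum allowed inter-chain atom distance (Angstrom);
#'   0 disables clash rejection.
#' @param seed Integer seed for the rotation set.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(rotation_count = 576, grid_spacing = 2,
                        clash_distance = 2.5, seed = 1) {
  if (rotation_count < 1) stop("rotation_count must be >= 1")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  structure(list(rotation_count = as.integer(rotation_count),
                 grid_spacing = grid_spacing,
                 clash_distance = clash_distance, seed = as.integer(seed)),
            class = "scan_config")
}

## Uniform random rotation matrices (Shoemake quaternion method), drawn from a
## private RNG stream so the surrounding session RNG state is untouched.
rotation_set <- function(n, seed) {
  rots <- vector("list", n)
  rots[[1]] <- diag(3)
  if (n > 1) {
    state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    U <- matrix(runif(3 * (n - 1)), ncol = 3)
    if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
    for (i in seq_len(n - 1)) {
      u1 <- U[i, 1]; u2 <- U[i, 2]; u3 <- U[i, 3]
      q <- c(sqrt(1 - u1) * sin(2 * pi * u2), sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3), sqrt(u1) * cos(2 * pi * u3))
      w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
      rots[[i + 1]] <- matrix(c(
        1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
        nrow = 3, byrow = TRUE)
    }
  }
  do.call(rbind, rots)
}

resolve_fixed_anchors <- function(fixed, restraints) {
  lapply(strsplit(restraints$fixed, "|", fixed = TRUE), function(sel) {
    anchor_coords(fixed, sel)
  })
}

resolve_scan_anchors <- function(scanning, restraints) {
  ## returns 0-based row index of the CA atom in the scanning structure
  vapply(restraints$scan, function(sel) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    hit <- which(scanning$chain == parts[1] &
                   scanning$resno == as.integer(parts[2]) &
                   scanning$elety == "CA")
    if (length(hit) == 0)
      stop("scan anchor '", sel, "' resolves to no CA atom")
    hit[1] - 1L
  }, integer(1), USE.NAMES = FALSE)
}

run_scan_kernel <- function(fixed, scanning, restraints, cfg,
                            contact_level = -1L, contact_cutoff = 5) {
  if (nrow(restraints) < 1) stop("at least one restraint is required")
  fx <- coord_matrix(fixed)
  sx <- coord_matrix(scanning)
  d_max <- max(restraints$d_max)
  gmin <- apply(fx, 2, min) - d_max
  gmax <- apply(fx, 2, max) + d_max
  gdim <- as.integer(floor((gmax - gmin) / cfg$grid_spacing)) + 1L
  rot <- rotation_set(cfg$rotation_count, cfg$seed)
  fres <- as.integer(factor(residue_key(fixed),
                            levels = unique(residue_key(fixed)))) - 1L
  sres <- as.integer(factor(residue_key(scanning),
                            levels = unique(residue_key(scanning)))) - 1L
  out <- .xlscan_cpp(fx, sx, fres, sres, rot, gmin, gdim, cfg$grid_spacing,
                     resolve_scan_anchors(scanning, restraints),
                     resolve_fixed_anchors(fixed, restraints),
                     restraints$d_min, restraints$d_max,
                     cfg$clash_distance, as.integer(contact_level),
                     contact_cutoff)
  out$fixed_residues <- unique(residue_key(fixed))
  out$scan_residues <- unique(residue_key(scanning))
  out
}

mask_popcounts <- function(n_restraints) {
  masks <- seq_len(2^n_restraints) - 1L
  vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n_restraints - 1))) > 0),
         integer(1))
}

#' Rigid-body accessible-interaction-space scan
#'
#' Enumerates rotation x translation poses of `scanning` around `fixed`,
#' rejects clashing poses, and tallies how many restraints each remaining
#' pose satisfies (minimum anchor distance over each restraint's ambiguity
#' set, within `[d_min, d_max]`).
#'
#' @param fixed,scanning `Structure`s.
#' @param restraints Restraint table from [distance_restraints()].
#' @param cfg A [scan_config()].
#' @param level Consistency level at which violated fractions are evaluated;
#'   `NULL` (default) uses `n_max - 1`.
#' @return List of class `xl_scan` with `accessible_counts` (named vector,
#'   poses satisfying >= N restraints for N = 0..n), `n_max` (highest N with
#'   a nonzero count), `violated_fraction` (per restraint, among poses at the
#'   evaluation level), `level`, and `poses_at_level`.
#' @export
restraint_scan <- function(fixed, scanning, restraints, cfg = scan_config(),
                 level = NULL) {
  kern <- run_scan_kernel(fixed, scanning, restraints, cfg)
  nR <- nrow(restraints)
  counts <- kern$mask_counts
  pc <- mask_popcounts(nR)
  accessible <- vapply(0:nR, function(N) sum(counts[pc >= N]), numeric(1))
  names(accessible) <- 0:nR
  n_max <- if (any(accessible[-1] > 0)) max(which(accessible[-1] > 0)) else 0L
  lev <- if (is.null(level)) max(n_max - 1L, 0L) else as.integer(level)
  at_level <- counts[pc >= lev]
  denom <- sum(at_level)
  viol <- vapply(seq_len(nR), function(r) {
    if (denom == 0) return(NA_real_)
    bit <- bitwShiftL(1L, r - 1L)
    masks <- which(pc >= lev) - 1L
    unsat <- masks[bitwAnd(masks, bit) == 0]
    sum(counts[unsat + 1L]) / denom
  }, numeric(1))
  names(viol) <- restraints$id
  structure(list(accessible_counts = accessible, n_max = n_max,
                 violated_fraction = viol, level = lev,
                 poses_at_level = denom, restraints = restraints,
                 config = cfg),
            class = "xl_scan")
}

#' @export
print.xl_scan <- function(x, ...) {
  cat("Accessible interaction space scan\n")
  cat("  non-clashing poses:", format(x$accessible_counts[["0"]]), "\n")
  cat("  n_max:", x$n_max, "; poses at level", x$level, ":",
      format(x$poses_at_level), "\n")
  cat("  violated fractions:\n")
  print(round(x$violated_fraction, 3))
  invisible(x)
}

#' Iterative discard of likely-false-positive restraints
#'
#' Repeats the scan, each round discarding restraints whose violated fraction
#' at the current consistency level reaches `discard_threshold`, until no
#' restraint is discarded or `max_rounds` is reached.
#'
#' @inheritParams restraint_scan
#' @param discard_threshold Violated-fraction threshold at or above which a
#'   restraint is discarded (default 0.8).
#' @param max_rounds Maximum number of scan rounds.
#' @return List with `kept` (restraint table), `discarded` (ids), `log`
#'   (per-round violated fractions), and `status` (`"ok"` or
#'   `"all_discarded"`).
#' @export
iterative_filter <- function(fixed, scanning, restraints,
                             cfg = scan_config(), discard_threshold = 0.8,
                             max_rounds = 10, level = NULL) {
  if (nrow(restraints) < 1) stop("at least one restraint is required")
  current <- restraints
  log <- list()
  discarded <- character()
  for (round in seq_len(max_rounds)) {
    res <- restraint_scan(fixed, scanning, current, cfg, level = level)
    drop <- which(!is.na(res$violated_fraction) &
                    res$violated_fraction >= discard_threshold)
    log[[round]] <- data.frame(round = round, id = current$id,
                               violated_fraction = res$violated_fraction,
                               discarded = seq_len(nrow(current)) %in% drop,
                               stringsAsFactors = FALSE)
    if (length(drop) == 0) break
    discarded <- c(discarded, current$id[drop])
    current <- current[-drop, , drop = FALSE]
    if (nrow(current) == 0) {
      warning("all restraints were discarded")
      return(list(kept = current, discarded = discarded,
                  log = do.call(rbind, log), status = "all_discarded"))
    }
  }
  list(kept = current, discarded = discarded, log = do.call(rbind, log),
       status = "ok")
}

#' Interaction fraction of candidate residues over accessible poses
#'
#' Among the non-clashing poses satisfying the maximum attainable number of
#' restraints, computes for each residue the fraction of poses in which it
#' makes an inter-chain contact within `contact_cutoff`. Selecting residues
#' (e.g. keeping those above 0.5 as docking-active) is left to the caller.
#'
#' @inheritParams restraint_scan
#' @param candidate_residues Character vector of `"chain:resno"` keys (on
#'   either chain) to report; `NULL` reports all residues.
#' @param contact_cutoff Contact distance in Angstrom.
#' @return data.frame with `residue`, `chain_role` (`"fixed"`/`"scanning"`)
#'   and `interaction_fraction`.
#' @export
interaction_fraction <- function(fixed, scanning, restraints,
                                 cfg = scan_config(),
                                 candidate_residues = NULL,
                                 contact_cutoff = 5) {
  first <- restraint_scan(fixed, scanning, restraints, cfg)
  if (first$n_max == 0 || first$accessible_counts[["0"]] == 0)
    stop("no accessible poses satisfy any restraint; ",
         "consider loosening the restraints or the clash distance")
  kern <- run_scan_kernel(fixed, scanning, restraints, cfg,
                          contact_level = first$n_max,
                          contact_cutoff = contact_cutoff)
  denom <- kern$qualifying_poses
  out <- rbind(
    data.frame(residue = kern$fixed_residues, chain_role = "fixed",
               interaction_fraction = kern$contact_fixed_res / denom,
               stringsAsFactors = FALSE),
    data.frame(residue = kern$scan_residues, chain_role = "scanning",
               interaction_fraction = kern$contact_scan_res / denom,
               stringsAsFactors = FALSE))
  if (!is.null(candidate_residues)) {
    miss <- setdiff(candidate_residues, out$residue)
    if (length(miss) > 0)
      stop("candidate residue(s) not in either chain: ",
           paste(miss, collapse = ", "))
    out <- out[out$residue %in% candidate_residues, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
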