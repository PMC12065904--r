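# Independent oracle implementations used to cross-check the package's
# geometry code. These deliberately avoid the code paths they verify.

# brute-force rigid superposition: quaternion grid + local refinement of
# Euler angles, never touching the package's Kabsch code
oracle_superpose_rmsd <- function(mobile, reference, n_grid = 4000) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rot_from_euler <- function(p) {
    cz <- cos(p[1]); sz <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cx <- cos(p[3]); sx <- sin(p[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) sqrt(mean(rowSums((A %*% t(rot_from_euler(p)) - B)^2)))
  set.seed(99)
  grid <- cbind(runif(n_grid, -pi, pi), runif(n_grid, -pi / 2, pi / 2),
                runif(n_grid, -pi, pi))
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt2 <- optim(opt$par, obj, method = "BFGS",
                control = list(reltol = 1e-14))
  min(opt$value, opt2$value)
}

# O(N^2) all-pairs contact oracle on two Structures
oracle_contacts <- function(a, b, cutoff, atom_class = "heavy") {
  sel <- function(s) {
    if (atom_class == "calpha") s <- s[s$elety == "CA", ]
    if (atom_class == "backbone") s <- s[s$elety %in% c("N", "CA", "C", "O"), ]
    s
  }
  a <- sel(a); b <- sel(b)
  pairs <- character()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                (a$z[i] - b$z[j])^2)
    if (d <= cutoff)
      pairs <- c(pairs, paste0(a$chain[i], ":", a$resno[i], "|",
                               b$chain[j], ":", b$resno[j]))
  }
  sort(unique(pairs))
}

# Monte Carlo SASA of one atom set (independent of the deterministic
# golden-spiral sampler): random points on each sphere
oracle_sasa_mc <- function(xyz, radii, probe = 1.4, n_mc = 20000, seed = 42) {
  set.seed(seed)
  r <- radii + probe
  total <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    z <- runif(n_mc, -1, 1)
    th <- runif(n_mc, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    pts <- cbind(s * cos(th), s * sin(th), z) * r[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(xyz))[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > r[j]^2
    }
    total[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

# plain-loop reimplementation of neighbour-count clustering from a distance
# matrix (declared rules: most neighbours wins, ties to lower index, cluster
# = centre + neighbours accepted at >= min_size total members)
oracle_cluster <- function(dmat, cutoff, min_size) {
  n <- nrow(dmat)
  remaining <- seq_len(n)
  clusters <- list()
  repeat {
    if (length(remaining) == 0) break
    counts <- sapply(remaining, function(i)
      sum(dmat[i, remaining] <= cutoff) - 1)
    b <- which.max(counts)
    if (counts[b] + 1 < min_size) break
    centre <- remaining[b]
    members <- remaining[dmat[centre, remaining] <= cutoff]
    clusters[[length(clusters) + 1]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  list(clusters = clusters, unclustered = remaining)
}

# tiny PDB text fixture writer
write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resn, chain, resno, x, y, z, occ, 0,
          substr(gsub("[0-9]", "", name), 1, 1))
}

# simple two-chain structure builder for docking fixtures
toy_two_chain <- function(shift_b = c(0, 0, 0)) {
  a <- data.frame(chain = "A", resno = 1:4, resid = "ALA",
                  elety = "CA", element = "C",
                  x = c(0, 3.8, 7.6, 11.4), y = 0, z = 0)
  b <- data.frame(chain = "B", resno = 1:3, resid = "ALA",
                  elety = "CA", element = "C",
                  x = c(2, 5.8, 9.6) + shift_b[1], y = 6 + shift_b[2],
                  z = 0 + shift_b[3])
  as_structure(rbind(a, b))
}

# cache toy complexes across test files (generation includes validation scans)
.toy_cache <- new.env(parent = emptyenv())
cached_toy <- function(seed, backbone = FALSE) {
  key <- paste0("s", seed, "_", backbone)
  if (is.null(.toy_cache[[key]]))
    .toy_cache[[key]] <- make_toy_complex(seed = seed, backbone = backbone)
  .toy_cache[[key]]
}
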