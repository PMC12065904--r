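# ensemble fixtures are cached: generation is seeded and deterministic
.ens_cache <- new.env(parent = emptyenv())
cached_ensemble <- function(seed, n_models = 10, n_clusters = 2) {
  key <- paste(seed, n_models, n_clusters)
  if (is.null(.ens_cache[[key]]))
    .ens_cache[[key]] <- make_toy_ensemble(seed = seed, n_models = n_models,
                                           n_clusters = n_clusters)
  .ens_cache[[key]]
}

simple_model <- function(shift_b = c(0, 0, 0), energies = NULL,
                         id = "m") {
  complex_model(toy_two_chain(shift_b), receptor_chains = "A",
                ligand_chain = "B", energies = energies, model_id = id)
}

test_that("haddock_score is the weighted energy sum", {
  m <- simple_model(energies = c(E_vdw = -10, E_elec = -100, E_desol = -5,
                                 E_air = 30))
  expect_equal(haddock_score(m), -32)
  zero <- simple_model(energies = c(E_vdw = 0, E_elec = 0, E_desol = 0,
                                    E_air = 0))
  expect_equal(haddock_score(zero), 0)
  expect_equal(haddock_score(m, weights = c(E_vdw = 1, E_elec = 1,
                                            E_desol = 1, E_air = 1)),
               sum(c(-10, -100, -5, 30)))
  noe <- simple_model()
  expect_error(haddock_score(noe), "E_vdw")
})

test_that("rmsd metrics vanish on self-comparison and detect a pure shift", {
  m <- simple_model()
  self <- rmsd_metrics(m, m, interface_cutoff = 8)
  expect_equal(unname(self), c(0, 0, 0), tolerance = 1e-9)

  shifted <- simple_model(shift_b = c(0, 0, 3))
  mm <- rmsd_metrics(shifted, m, interface_cutoff = 8)
  expect_equal(unname(mm["l_rmsd"]), 3, tolerance = 1e-9)
  expect_gt(mm["global_rmsd"], 0)
})

test_that("i-RMSD matches an independent two-step oracle", {
  te <- cached_ensemble(5)
  ref <- te$ensemble$models[[1]]
  mod <- te$ensemble$models[[3]]
  got <- rmsd_metrics(mod, ref, interface_cutoff = 10)

  # oracle: explicit interface extraction + bio3d superposition
  iface <- oracle_contacts(
    betactin::structure_chains(ref$structure, c("A", "C")),
    betactin::structure_chains(ref$structure, "B"), 10)
  res_keys <- unique(unlist(strsplit(iface, "|", fixed = TRUE)))
  sel <- function(s) {
    k <- paste0(s$chain, ":", s$resno)
    s[k %in% res_keys & s$elety %in% c("N", "CA", "C", "O"), ]
  }
  A <- sel(mod$structure); B <- sel(ref$structure)
  stopifnot(identical(paste(A$chain, A$resno, A$elety),
                      paste(B$chain, B$resno, B$elety)))
  xyzB <- as.vector(t(as.matrix(B[, c("x", "y", "z")])))
  xyzA <- as.vector(t(as.matrix(A[, c("x", "y", "z")])))
  fitted <- bio3d::fit.xyz(xyzB, xyzA, fixed.inds = seq_along(xyzB),
                           mobile.inds = seq_along(xyzA))
  i_oracle <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) -
       matrix(xyzB, ncol = 3, byrow = TRUE))^2)))
  expect_equal(unname(got["i_rmsd"]), i_oracle, tolerance = 1e-6)
})

test_that("l-RMSD matches a two-step receptor-fit oracle", {
  te <- cached_ensemble(5)
  ref <- te$ensemble$models[[1]]
  mod <- te$ensemble$models[[2]]
  got <- rmsd_metrics(mod, ref)
  bb <- function(s, chains) {
    s <- s[s$chain %in% chains & s$elety %in% c("N", "CA", "C", "O"), ]
    s[order(s$chain, s$resno, s$elety), ]
  }
  rec_m <- bb(mod$structure, c("A", "C")); rec_r <- bb(ref$structure, c("A", "C"))
  lig_m <- bb(mod$structure, "B"); lig_r <- bb(ref$structure, "B")
  xyz <- function(s) as.vector(t(as.matrix(s[, c("x", "y", "z")])))
  fitted <- bio3d::fit.xyz(xyz(rec_r), xyz(rec_m),
                           fixed.inds = seq_along(xyz(rec_r)),
                           mobile.inds = seq_along(xyz(rec_m)))
  # apply the same transform to the ligand: refit full coords
  all_m <- rbind(rec_m, lig_m); all_r <- rbind(rec_r, lig_r)
  fitted_all <- bio3d::fit.xyz(xyz(all_r), xyz(all_m),
                               fixed.inds = 1:(nrow(rec_r) * 3),
                               mobile.inds = 1:(nrow(rec_m) * 3))
  lig_idx <- (nrow(rec_m) * 3 + 1):(nrow(all_m) * 3)
  l_oracle <- sqrt(mean(rowSums(
    (matrix(fitted_all[lig_idx], ncol = 3, byrow = TRUE) -
       as.matrix(lig_r[, c("x", "y", "z")]))^2)))
  expect_equal(unname(got["l_rmsd"]), l_oracle, tolerance = 1e-6)
})

test_that("flexible interface reduces to contacts for one model and unions over models", {
  te <- cached_ensemble(5)
  e1 <- ensemble(te$ensemble$models[1])
  cc <- contacts(structure_chains(te$ensemble$models[[1]]$structure, c("A", "C")),
                 structure_chains(te$ensemble$models[[1]]$structure, "B"), 10)
  expect_setequal(flexible_interface(e1, 10), unique(c(cc$res_a, cc$res_b)))

  # union property over the ensemble
  per_model <- lapply(te$ensemble$models, function(m)
    flexible_interface(ensemble(list(m)), 10))
  expect_setequal(flexible_interface(te$ensemble, 10),
                  unique(unlist(per_model)))
})

test_that("clustering matches the brute-force oracle and handles edge cases", {
  te <- cached_ensemble(5)
  iface <- flexible_interface(te$ensemble, 10)
  M <- il_rmsd_matrix(te$ensemble, iface)
  cl <- cluster_ensemble(te$ensemble, cutoff = 7.5, min_neighbors = 4,
                         dmat = M)
  oracle <- oracle_cluster(M, 7.5, 4)
  ids <- vapply(te$ensemble$models, `[[`, "", "model_id")
  got_sets <- lapply(cl$clusters, sort)
  oracle_sets <- lapply(oracle$clusters, function(i) sort(ids[i]))
  expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                  vapply(oracle_sets, paste, "", collapse = ","))
  expect_setequal(cl$unclustered, ids[oracle$unclustered])
  # planted membership is recovered
  expect_equal(length(cl$clusters), 2)
  expect_setequal(cl$clusters[[1]],
                  ids[te$membership == te$membership[
                    match(cl$centers[1], ids)]])

  # 6 mutually close models -> one cluster of 6
  M6 <- matrix(1, 6, 6); diag(M6) <- 0
  dimnames(M6) <- list(paste0("m", 1:6), paste0("m", 1:6))
  e6 <- ensemble(te$ensemble$models[rep(1, 6)])
  for (i in 1:6) e6$models[[i]]$model_id <- paste0("m", i)
  cl6 <- suppressWarnings(cluster_ensemble(e6, dmat = M6))
  expect_equal(lengths(cl6$clusters), 6)

  # 3 isolated models cannot reach the size floor
  M3 <- matrix(100, 3, 3); diag(M3) <- 0
  dimnames(M3) <- list(paste0("m", 1:3), paste0("m", 1:3))
  e3 <- ensemble(te$ensemble$models[rep(1, 3)])
  for (i in 1:3) e3$models[[i]]$model_id <- paste0("m", i)
  cl3 <- suppressWarnings(cluster_ensemble(e3, dmat = M3))
  expect_equal(length(cl3$clusters), 0)
  expect_equal(length(cl3$unclustered), 3)
})

test_that("cluster ranking uses the average of the four best member scores", {
  te <- cached_ensemble(5)
  cl <- cluster_ensemble(te$ensemble, iface_cutoff = 10)
  scores <- vapply(te$ensemble$models, haddock_score, numeric(1))
  names(scores) <- vapply(te$ensemble$models, `[[`, "", "model_id")
  manual <- vapply(cl$clusters, function(mem)
    mean(sort(scores[mem])[1:min(4, length(mem))]), numeric(1))
  expect_equal(cl$scores, manual)
  expect_true(!is.unsorted(cl$scores))
})

test_that("restraint_check classifies the 30/35 A bands and matches direct distances", {
  te <- cached_ensemble(5)
  toy <- te$toy
  rc <- restraint_check(te$ensemble, toy$restraints_true)
  expect_true(all(abs(rowSums(rc$fractions) - 1) < 1e-12))

  # direct per-model recomputation oracle
  m1 <- te$ensemble$models[[1]]$structure
  k <- paste0(m1$chain, ":", m1$resno)
  r1 <- toy$restraints_true[1, ]
  alts <- strsplit(r1$fixed, "|", fixed = TRUE)[[1]]
  dist1 <- min(vapply(alts, function(a) {
    fa <- m1[k == a & m1$elety == "CA", ]
    sc <- m1[k == r1$scan & m1$elety == "CA", ]
    sqrt((fa$x - sc$x)^2 + (fa$y - sc$y)^2 + (fa$z - sc$z)^2)
  }, numeric(1)))
  expect_equal(unname(rc$distances[1, 1]), dist1, tolerance = 1e-9)

  # band rule: 33 A is tolerated, not violated
  m <- simple_model()
  wide <- complex_model(toy_two_chain(c(0, 27, 0)), "A", "B", model_id = "w")
  e2 <- ensemble(list(wide))
  rcw <- restraint_check(e2, distance_restraints("A:1", "B:1"))
  d <- unname(rcw$distances[1, 1])
  expect_true(d > 30 && d <= 35)
  expect_equal(unname(rcw$fractions[1, ]),
               c(satisfied = 0, tolerated = 1, violated = 0),
               ignore_attr = TRUE)
})

test_that("contact frequency averages per-model contacts and is monotone in the cutoff", {
  te <- cached_ensemble(5)
  cf <- contact_frequency(te$ensemble, 8)
  per_model <- lapply(te$ensemble$models, function(m) {
    cc <- contacts(structure_chains(m$structure, c("A", "C")),
                   structure_chains(m$structure, "B"), 8)
    unique(c(cc$res_a, cc$res_b))
  })
  for (i in seq_len(nrow(cf))) {
    oracle <- mean(vapply(per_model, function(s) cf$residue[i] %in% s,
                          logical(1)))
    expect_equal(cf$frequency[i], oracle)
  }
  expect_true(all(cf$frequency >= 0 & cf$frequency <= 1))

  cf2 <- contact_frequency(te$ensemble, 10)
  common <- intersect(cf$residue, cf2$residue)
  expect_true(all(cf2$frequency[match(common, cf2$residue)] >=
                    cf$frequency[match(common, cf$residue)]))
})

test_that("average_structure averages after receptor fit", {
  te <- cached_ensemble(5)
  m <- te$ensemble$models[[1]]
  # identical models average to themselves
  avg <- average_structure(list(m, m))
  expect_equal(avg$x, m$structure$x, tolerance = 1e-9)

  # ligand shifted +/- 1 A along x with fixed receptor -> midpoint
  base <- toy_two_chain()
  p <- complex_model(base, "A", "B", model_id = "p")
  plus <- complex_model(toy_two_chain(c(1, 0, 0)), "A", "B", model_id = "+")
  minus <- complex_model(toy_two_chain(c(-1, 0, 0)), "A", "B", model_id = "-")
  avg2 <- average_structure(list(p, plus, minus))
  expect_equal(avg2$x, base$x, tolerance = 1e-9)

  # element-wise oracle for four models after identical receptor fits
  models <- te$ensemble$models[1:4]
  ref <- models[[1]]
  acc <- as.matrix(ref$structure[, c("x", "y", "z")])
  for (mm in models[-1]) {
    bb <- function(s) {
      sel <- s$chain %in% c("A", "C") & s$elety %in% c("N", "CA", "C", "O")
      as.matrix(s[sel, c("x", "y", "z")])
    }
    fit <- superpose(bb(mm$structure), bb(ref$structure))
    acc <- acc + apply_transform(as.matrix(mm$structure[, c("x", "y", "z")]),
                                 fit)
  }
  avg4 <- average_structure(models)
  expect_equal(as.matrix(avg4[, c("x", "y", "z")]), acc / 4,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("compare_to_reference handles identity maps and identity percentages", {
  m <- simple_model()
  keys <- unique(paste0(m$structure$chain, ":", m$structure$resno))
  map <- data.frame(candidate = keys, reference = keys)
  got <- compare_to_reference(m, m, map, interface_cutoff = 8)
  expect_equal(got$l_rmsd, 0, tolerance = 1e-9)
  expect_equal(got$i_rmsd, 0, tolerance = 1e-9)
  expect_equal(got$interface_identity, 100)

  # one of four mapped interface positions differs in residue type -> 75%
  cand <- m$structure
  iface <- c("A:2", "A:3", "B:1", "B:2")
  cand$resid[paste0(cand$chain, ":", cand$resno) == "B:1"] <- "GLY"
  m2 <- complex_model(as_structure(cand), "A", "B", model_id = "mut")
  got2 <- compare_to_reference(
    m2, m, map, interface_cutoff = 8)
  # expected percentage from the actual interface at this cutoff
  cc <- contacts(structure_chains(m$structure, "A"),
                 structure_chains(m$structure, "B"), 8)
  ir <- unique(c(cc$res_a, cc$res_b))
  expected <- 100 * mean(ir != "B:1")
  expect_equal(got2$interface_identity, expected)
})
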