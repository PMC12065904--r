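# unit tests use a reduced sampling configuration; the full default-sampling
# recovery run lives in the acceptance suite
# (2 A spacing is kept so the grid-aligned planted pose stays clash-free and
# within the restraint bounds; the rotation count is what is reduced)
fast_cfg <- function(...) scan_config(rotation_count = 48, grid_spacing = 2,
                                      ...)

single_atom <- function(chain, x, y, z) {
  as_structure(data.frame(chain = chain, resno = 1, resid = "ALA",
                          elety = "CA", element = "C", x = x, y = y, z = z))
}

test_that("translation-only accessible counts equal the grid-enumeration oracle", {
  fx <- single_atom("A", 0, 0, 0)
  sc <- single_atom("B", 5, 5, 5)
  r <- distance_restraints("A:1", "B:1")
  res <- restraint_scan(fx, sc, r,
                        scan_config(rotation_count = 1, grid_spacing = 2,
                                    clash_distance = 0))
  g <- expand.grid(x = seq(-30, 30, 2), y = seq(-30, 30, 2),
                   z = seq(-30, 30, 2))
  oracle <- sum(sqrt(rowSums(g^2)) <= 30)
  expect_equal(unname(res$accessible_counts[["1"]]), oracle)
  # and with a clash sphere the inner shell is excluded
  res2 <- restraint_scan(fx, sc, r,
                         scan_config(rotation_count = 1, grid_spacing = 2,
                                     clash_distance = 2.5))
  oracle2 <- sum(sqrt(rowSums(g^2)) <= 30 & sqrt(rowSums(g^2)) >= 2.5)
  expect_equal(unname(res2$accessible_counts[["1"]]), oracle2)
})

test_that("all planted restraints hold simultaneously in the planted pose", {
  toy <- cached_toy(2)
  res <- restraint_scan(toy$fixed, toy$scanning, toy$restraints_true,
                        fast_cfg())
  expect_equal(res$n_max, nrow(toy$restraints_true))
})

test_that("a geometrically impossible restraint has violated fraction 1", {
  toy <- cached_toy(2)
  both <- rbind(toy$restraints_true, toy$restraints_false)
  res <- restraint_scan(toy$fixed, toy$scanning, both, fast_cfg())
  expect_equal(res$n_max, nrow(toy$restraints_true))
  vf <- res$violated_fraction
  expect_equal(unname(vf[toy$restraints_false$id]), c(1, 1))
})

test_that("ambiguous anchors are satisfied by the minimum over the set", {
  fx <- as_structure(data.frame(
    chain = c("A", "C"), resno = 1, resid = "ALA", elety = "CA",
    element = "C", x = c(0, 100), y = 0, z = 0))
  sc <- single_atom("B", 20, 0, 0)
  amb <- distance_restraints("A:1|C:1", "B:1")
  cfg <- scan_config(rotation_count = 1, grid_spacing = 2,
                     clash_distance = 0)
  res <- restraint_scan(fx, sc, amb, cfg)
  una <- restraint_scan(fx, sc, distance_restraints("A:1", "B:1"), cfg)
  # ambiguity adds the second 30 A sphere around C:1
  expect_gt(res$accessible_counts[["1"]], una$accessible_counts[["1"]])
})

test_that("scan is deterministic and invariant to restraint order", {
  toy <- cached_toy(3)
  both <- rbind(toy$restraints_true, toy$restraints_false)
  r1 <- restraint_scan(toy$fixed, toy$scanning, both, fast_cfg())
  r2 <- restraint_scan(toy$fixed, toy$scanning, both, fast_cfg())
  expect_identical(r1$accessible_counts, r2$accessible_counts)
  perm <- both[rev(seq_len(nrow(both))), ]
  r3 <- restraint_scan(toy$fixed, toy$scanning, perm, fast_cfg())
  expect_equal(r1$accessible_counts, r3$accessible_counts)
  expect_equal(r1$violated_fraction[both$id], r3$violated_fraction[both$id])
})

test_that("adding a restraint never enlarges the fully-consistent space", {
  toy <- cached_toy(3)
  rt <- toy$restraints_true
  res_sub <- restraint_scan(toy$fixed, toy$scanning, rt[1:5, ], fast_cfg())
  res_all <- restraint_scan(toy$fixed, toy$scanning, rt, fast_cfg())
  expect_lte(res_all$accessible_counts[["10"]],
             res_sub$accessible_counts[["5"]])
})

test_that("iterative_filter removes exactly the planted false positives", {
  toy <- cached_toy(2)
  both <- rbind(toy$restraints_true, toy$restraints_false)
  flt <- iterative_filter(toy$fixed, toy$scanning, both, fast_cfg(),
                          discard_threshold = 0.8)
  expect_setequal(flt$discarded, toy$restraints_false$id)
  expect_setequal(flt$kept$id, toy$restraints_true$id)
  expect_equal(flt$status, "ok")

  # all-true input is a fixed point
  flt2 <- iterative_filter(toy$fixed, toy$scanning, toy$restraints_true,
                           fast_cfg())
  expect_equal(flt2$kept$id, toy$restraints_true$id)
  expect_equal(max(flt2$log$round), 1)

  # threshold 0 discards everything in round one
  expect_warning(
    flt3 <- iterative_filter(toy$fixed, toy$scanning, both, fast_cfg(),
                             discard_threshold = 0),
    "all restraints")
  expect_equal(flt3$status, "all_discarded")
})

test_that("interaction fractions separate interface from far-side residues", {
  toy <- cached_toy(2)
  fr <- interaction_fraction(toy$fixed, toy$scanning, toy$restraints_true,
                             fast_cfg(), contact_cutoff = 10)
  # planted-interface residues (in contact in the planted pose)
  cc <- contacts(toy$fixed, toy$scanning, cutoff = 9.5)
  iface_res <- unique(c(cc$res_a, cc$res_b))
  # far side: fixed bead farthest from the ligand centroid
  fx <- toy$fixed
  cen <- colMeans(as.matrix(toy$scanning[, c("x", "y", "z")]))
  d <- sqrt((fx$x - cen[1])^2 + (fx$y - cen[2])^2 + (fx$z - cen[3])^2)
  far_res <- paste0(fx$chain[which.max(d)], ":", fx$resno[which.max(d)])
  get <- function(res) fr$interaction_fraction[fr$residue %in% res]
  expect_gt(max(get(iface_res)), 0.5)
  expect_lt(get(far_res), 0.1)
})

test_that("interaction_fraction errors when no pose satisfies any restraint", {
  fx <- single_atom("A", 0, 0, 0)
  sc <- single_atom("B", 5, 5, 5)
  r <- distance_restraints("A:1", "B:1", d_min = 0, d_max = 0.1)
  expect_error(
    interaction_fraction(fx, sc, r,
                         scan_config(rotation_count = 1, grid_spacing = 2)),
    "no accessible poses")
})

test_that("restraint tables round-trip through CSV", {
  toy <- cached_toy(1)
  path <- tempfile(fileext = ".csv")
  write.csv(rbind(toy$restraints_true, toy$restraints_false), path,
            row.names = FALSE)
  back <- read_restraints(path)
  expect_equal(back$fixed, c(toy$restraints_true$fixed,
                             toy$restraints_false$fixed))
  expect_equal(back$d_max, rep(30, nrow(back)))
})
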