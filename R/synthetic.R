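## Seeded synthetic-data generators.
##
## Every generator is a pure function of (seed, parameters): the same call
## reproduces the same output byte for byte, and outputs are emitted in the
## exact formats the analysis modules consume. Pseudo-structures are
## Calpha-only chains on compact backbone-like curves (optionally decorated
## with dummy N/C/O backbone atoms); they emulate the geometry the structural
## stages assume (two adjacent filament subunits as the fixed chain, one
## ligand chain, planted binding pose, true cross-links within reach and
## planted false positives far out of reach), not real protein folds.

## compact self-avoiding chain: n beads, 3.8 A steps, confined to an
## ellipsoid with the given semi-axes. assumes the RNG is already seeded by
## the caller.
compact_chain <- function(n, axes, center) {
  axes <- rep_len(axes, 3)
  for (attempt in 1:50) {
    pts <- matrix(NA_real_, n, 3)
    pts[1, ] <- center + runif(3, -1, 1)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:300) {
        dir <- rnorm(3)
        cand <- pts[i - 1, ] + 3.8 * dir / sqrt(sum(dir^2))
        if (sum(((cand - center) / axes)^2) > 1) next
        if (i > 2) {
          d2 <- rowSums(sweep(pts[1:(i - 2), , drop = FALSE], 2, cand)^2)
          if (min(d2) < 3.5^2) next
        }
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  stop("could not generate a compact chain; loosen the confinement")
}

chain_structure <- function(pts, chain, backbone = FALSE, resid = "ALA") {
  n <- nrow(pts)
  rows <- list(data.frame(chain = chain, resno = seq_len(n), resid = resid,
                          elety = "CA", element = "C", x = pts[, 1],
                          y = pts[, 2], z = pts[, 3],
                          stringsAsFactors = FALSE))
  if (backbone) {
    ## dummy backbone atoms offset along the local chain direction
    dirs <- rbind(pts[2, ] - pts[1, ],
                  if (n > 2) pts[3:n, , drop = FALSE] -
                    pts[1:(n - 2), , drop = FALSE] else NULL,
                  pts[n, ] - pts[n - 1, ])
    dirs <- dirs / sqrt(rowSums(dirs^2))
    up <- cbind(-dirs[, 2], dirs[, 1], rep(0.3, n))
    up <- up / sqrt(rowSums(up^2))
    for (at in list(c("N", "N", -1.45), c("C", "C", 1.52))) {
      off <- pts + as.numeric(at[3]) * dirs
      rows[[length(rows) + 1]] <-
        data.frame(chain = chain, resno = seq_len(n), resid = resid,
                   elety = at[1], element = at[2], x = off[, 1],
                   y = off[, 2], z = off[, 3], stringsAsFactors = FALSE)
    }
    offo <- pts + 1.52 * dirs + 1.2 * up
    rows[[length(rows) + 1]] <-
      data.frame(chain = chain, resno = seq_len(n), resid = resid,
                 elety = "O", element = "O", x = offo[, 1], y = offo[, 2],
                 z = offo[, 3], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$resno, match(df$elety, c("N", "CA", "C", "O"))), ]
  new_structure(df)
}

min_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Generate a planted two-chain toy complex with cross-links
#'
#' Builds a fixed chain of two adjacent pseudo-subunits (chains A and C,
#' mimicking filament subunits n and n+2), a scanning ligand chain (B)
#' planted clash-free over the groove between them, true cross-link
#' restraints whose anchor distance in the planted pose lies in
#' `[true_min, true_max]`, and planted false-positive restraints that are
#' geometrically impossible to satisfy jointly with the true set: each false
#' pair is at least `false_min` away in the planted pose and conflicts by
#' triangle inequality (fixed-anchor gap exceeding `2 * d_max` plus the
#' intra-ligand anchor span) with at least `min_conflicts` true restraints,
#' so no rigid pose can satisfy it together with those.
#'
#' With `ambiguous = TRUE` the true restraints use subunit-ambiguous anchors
#' (`A:i|C:i`, minimum over the pair), exercising the ambiguity machinery;
#' note that ambiguous anchors weaken the restraints so false-positive
#' recovery is then no longer guaranteed.
#'
#' @param seed Integer seed.
#' @param n_per_subunit,n_scan Pseudo-residues per fixed subunit / in the
#'   ligand.
#' @param n_true,n_false Numbers of planted true and false restraints.
#' @param true_min,true_max,false_min Distance design (Angstrom).
#' @param min_conflicts Minimum number of true restraints each planted false
#'   positive is incompatible with.
#' @param ambiguous Use subunit-ambiguous anchors for the true restraints.
#' @param backbone Add dummy N/C/O backbone atoms (needed for backbone-based
#'   docking metrics).
#' @param dir Optional directory; when given, `fixed.pdb`, `scanning.pdb`
#'   and `restraints.csv` are written there.
#' @return List with `fixed`, `scanning` (Structures), `restraints_true`,
#'   `restraints_false` (restraint tables), `planted_pose` (identity: the
#'   scanning chain is generated in its bound pose).
#' @export
make_toy_complex <- function(seed = 1, n_per_subunit = 60, n_scan = 50,
                             n_true = 10, n_false = 2, true_min = 8,
                             true_max = 28, false_min = 45,
                             min_conflicts = 4, ambiguous = FALSE,
                             backbone = FALSE, dir = NULL) {
  d_max <- 30
  with_local_seed(seed, {
    ## regenerate until the planted geometry admits the requested design:
    ## a clash-free interface pose, enough in-reach pairs for the true
    ## cross-links and conflicting far pairs for the planted false positives
    done <- FALSE
    for (build in 1:60) {
      ## elongated subunits (like filament subunits seen side-on), ligand
      ## planted over the groove between them
      sub_a <- compact_chain(n_per_subunit, axes = c(20, 10, 10),
                             center = c(0, 0, 0))
      sub_c <- compact_chain(n_per_subunit, axes = c(20, 10, 10),
                             center = c(48, 0, 0))
      fixed_pts <- rbind(sub_a, sub_c)
      scan_pts <- NULL
      for (attempt in 1:50) {
        cand <- compact_chain(n_scan, axes = c(16, 8, 8),
                              center = c(24, 19, 0))
        dmin <- min_cross_dist(cand, fixed_pts)
        clearance <- apply(dmin, 1, min)
        if (min(clearance) >= 4.6 && sum(clearance <= 9.5) >= 4) {
          scan_pts <- cand
          break
        }
      }
      if (is.null(scan_pts)) next
      dfix <- min_cross_dist(scan_pts, fixed_pts)   # scan x all fixed beads
      in_range <- which(dfix >= true_min & dfix <= true_max, arr.ind = TRUE)
      if (nrow(in_range) < n_true) next
      pick_distinct <- function(cand, n, used_s = integer(),
                                used_f = integer()) {
        for (try in 1:50) {
          out <- integer(); us <- used_s; uf <- used_f
          for (i in sample(nrow(cand))) {
            if (cand[i, 1] %in% us || cand[i, 2] %in% uf) next
            out <- c(out, i)
            us <- c(us, cand[i, 1]); uf <- c(uf, cand[i, 2])
            if (length(out) == n) return(cand[out, , drop = FALSE])
          }
        }
        NULL
      }
      if (n_false > 0) {
        ## choose the false positives first, then guarantee each conflicts
        ## with >= min_conflicts picked true restraints: a conflict means the
        ## fixed-anchor gap exceeds 2*d_max plus the intra-ligand anchor
        ## span, so no rigid pose can satisfy both restraints
        lig_d <- min_cross_dist(scan_pts, scan_pts)
        fix_d <- min_cross_dist(fixed_pts, fixed_pts)
        far <- which(dfix >= false_min, arr.ind = TRUE)
        if (nrow(far) < n_false) next
        conflict_set <- function(b, f)
          which(fix_d[f, in_range[, 2]] - lig_d[b, in_range[, 1]] >
                  2 * d_max + 2)
        csets <- lapply(seq_len(nrow(far)),
                        function(i) conflict_set(far[i, 1], far[i, 2]))
        ord <- order(-lengths(csets))
        fa_rows <- integer(); used_s <- integer(); used_f <- integer()
        for (i in ord) {
          if (length(csets[[i]]) < 3 * min_conflicts) break
          if (far[i, 1] %in% used_s || far[i, 2] %in% used_f) next
          fa_rows <- c(fa_rows, i)
          used_s <- c(used_s, far[i, 1]); used_f <- c(used_f, far[i, 2])
          if (length(fa_rows) == n_false) break
        }
        if (length(fa_rows) < n_false) next
        fa <- far[fa_rows, , drop = FALSE]
        ## true picks: min_conflicts from each false positive's conflict
        ## set, the remainder unconstrained
        tr <- NULL
        ok <- TRUE
        for (i in fa_rows) {
          cand_rows <- in_range[csets[[i]], , drop = FALSE]
          pk <- pick_distinct(cand_rows, min_conflicts, used_s, used_f)
          if (is.null(pk)) { ok <- FALSE; break }
          tr <- rbind(tr, pk)
          used_s <- c(used_s, pk[, 1]); used_f <- c(used_f, pk[, 2])
        }
        if (!ok) next
        n_rest <- n_true - nrow(tr)
        if (n_rest < 0) next
        if (n_rest > 0) {
          pk <- pick_distinct(in_range, n_rest, used_s, used_f)
          if (is.null(pk)) next
          tr <- rbind(tr, pk)
        }
      } else {
        fa <- matrix(0L, 0, 2)
        tr <- pick_distinct(in_range, n_true)
        if (is.null(tr)) next
      }
      ## build the restraint tables and validate the planted design with a
      ## reduced-sampling scan: n_max must equal the true-set size, planted
      ## false positives must be (near-)always violated at level n_max - 1,
      ## and no planted-true restraint may itself look like a weak link
      anchor_label <- function(fidx) {
        sub <- ifelse(fidx <= n_per_subunit, "A", "C")
        res <- ifelse(fidx <= n_per_subunit, fidx, fidx - n_per_subunit)
        if (ambiguous) paste0("A:", res, "|C:", res)
        else paste0(sub, ":", res)
      }
      restraints_true <- distance_restraints(
        fixed = anchor_label(tr[, 2]), scan = paste0("B:", tr[, 1]),
        id = paste0("true", seq_len(n_true)))
      restraints_false <- if (nrow(fa) > 0) distance_restraints(
        fixed = ifelse(fa[, 2] <= n_per_subunit,
                       paste0("A:", fa[, 2]),
                       paste0("C:", fa[, 2] - n_per_subunit)),
        scan = paste0("B:", fa[, 1]),
        id = paste0("false", seq_len(n_false))) else
          distance_restraints(character(), character())
      if (!ambiguous) {
        fixed_ca <- new_structure(rbind(chain_structure(sub_a, "A"),
                                        chain_structure(sub_c, "C")))
        scan_ca <- chain_structure(scan_pts, "B")
        val <- restraint_scan(fixed_ca, scan_ca,
                              rbind(restraints_true, restraints_false),
                              scan_config(rotation_count = 24,
                                          grid_spacing = 2, seed = 7))
        vf <- val$violated_fraction
        if (val$n_max != n_true) next
        if (any(vf[restraints_true$id] > 0.4)) next
        if (n_false > 0 && any(vf[restraints_false$id] < 0.98)) next
      }
      done <- TRUE
      break
    }
    if (!done)
      stop("could not plant a toy complex for this design; ",
           "relax the distance design or chain sizes")
    fixed <- rbind(chain_structure(sub_a, "A", backbone),
                   chain_structure(sub_c, "C", backbone))
    fixed <- new_structure(fixed)
    scanning <- chain_structure(scan_pts, "B", backbone)
    if (!is.null(dir)) {
      write_pdb(fixed, file.path(dir, "fixed.pdb"))
      write_pdb(scanning, file.path(dir, "scanning.pdb"))
      write.csv(rbind(restraints_true, restraints_false),
                file.path(dir, "restraints.csv"), row.names = FALSE)
    }
    list(fixed = fixed, scanning = scanning,
         restraints_true = restraints_true,
         restraints_false = restraints_false,
         planted_pose = "identity")
  })
}

#' Generate cross-link reports with a designed provenance structure
#'
#' Residue pairs are assigned to engine/linker membership exactly per
#' `design` and emitted in the normalized report schema, one row per
#' (pair, engine, linker, replicate).
#'
#' @param design data.frame with columns `engines` (semicolon-joined engine
#'   set), `linkers` (semicolon-joined linker set) and `count`. Categories
#'   must be distinct.
#' @param replicates Replicate labels cycled over the emitted rows.
#' @param proteins Length-2 protein identifiers (pairs are inter-protein).
#' @param seed Integer seed (residue numbers are drawn deterministically).
#' @param dir Optional directory: one CSV per engine is written.
#' @return Normalized records data.frame (as from [parse_reports()]), with
#'   the generating pair table attached as attribute `pairs`.
#' @export
make_xlink_reports <- function(design, replicates = c("r1", "r2"),
                               proteins = c("CAVB2", "ACTIN"), seed = 1,
                               dir = NULL) {
  if (any(design$count < 0)) stop("counts must be non-negative")
  catkey <- paste(design$engines, design$linkers)
  if (anyDuplicated(catkey)) stop("overlapping category definitions")
  n_pairs <- sum(design$count)
  if (n_pairs == 0) {
    rec <- data.frame(protein_a = character(), residue_a = integer(),
                      protein_b = character(), residue_b = integer(),
                      linker = character(), engine = character(),
                      replicate = character(), link_class = character(),
                      stringsAsFactors = FALSE)
    attr(rec, "pairs") <- NULL
    return(rec)
  }
  with_local_seed(seed, {
    res_a <- sample(1:400, n_pairs)
    res_b <- sample(1:375, n_pairs)
    idx <- 0
    rows <- list()
    pairs <- list()
    for (i in seq_len(nrow(design))) {
      if (design$count[i] == 0) next
      engines <- strsplit(design$engines[i], ";", fixed = TRUE)[[1]]
      linkers <- strsplit(design$linkers[i], ";", fixed = TRUE)[[1]]
      for (j in seq_len(design$count[i])) {
        idx <- idx + 1
        pairs[[idx]] <- data.frame(residue_a = res_a[idx],
                                   residue_b = res_b[idx],
                                   engines = design$engines[i],
                                   linkers = design$linkers[i],
                                   stringsAsFactors = FALSE)
        for (en in engines) for (li in linkers) {
          rows[[length(rows) + 1]] <- data.frame(
            protein_a = proteins[1], residue_a = res_a[idx],
            protein_b = proteins[2], residue_b = res_b[idx],
            linker = li, engine = en,
            replicate = replicates[1 + (idx %% length(replicates))],
            stringsAsFactors = FALSE)
        }
      }
    }
    rec <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    rec$link_class <- "inter"
    if (!is.null(dir)) {
      for (en in unique(rec$engine))
        write.csv(rec[rec$engine == en,
                      c("protein_a", "residue_a", "protein_b", "residue_b",
                        "linker", "engine", "replicate")],
                  file.path(dir, paste0("report_", en, ".csv")),
                  row.names = FALSE)
    }
    attr(rec, "pairs") <- do.call(rbind, pairs)
    rec
  })
}

#' Generate a consensus alanine-scanning ddG table with planted hotspots
#'
#' Gaussian draws per (residue, predictor, model): hotspot residues around
#' `effect` kcal/mol, background residues around `background`.
#'
#' @param hotspots,background_res Residue numbers (on `chain`).
#' @param effect,effect_sd,background,background_sd Means and SDs (kcal/mol);
#'   defaults 2.0 +/- 0.3 vs 0.0 +/- 0.2.
#' @param predictors,models Numbers of predictors and docked structures
#'   (defaults 6 and 4).
#' @param chain Chain label.
#' @param seed Integer seed.
#' @return Long-format ddG table ([read_ddg_table()] schema) with the truth
#'   attached as attribute `truth`.
#' @export
make_ddg_tables <- function(hotspots, background_res, effect = 2.0,
                            effect_sd = 0.3, background = 0.0,
                            background_sd = 0.2, predictors = 6, models = 4,
                            chain = "B", seed = 1) {
  with_local_seed(seed, {
    res <- c(hotspots, background_res)
    mu <- c(rep(effect, length(hotspots)),
            rep(background, length(background_res)))
    sdv <- c(rep(effect_sd, length(hotspots)),
             rep(background_sd, length(background_res)))
    grid <- expand.grid(ri = seq_along(res),
                        predictor = paste0("P", seq_len(predictors)),
                        model_id = paste0("m", seq_len(models)),
                        stringsAsFactors = FALSE)
    out <- data.frame(chain = chain, resnum = res[grid$ri], restype = "LYS",
                      predictor = grid$predictor, model_id = grid$model_id,
                      ddg = rnorm(nrow(grid), mu[grid$ri], sdv[grid$ri]),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(resnum = res, mean_ddg = mu,
                                     hotspot = c(rep(TRUE, length(hotspots)),
                                                 rep(FALSE,
                                                     length(background_res))))
    out
  })
}

#' Simulate repeated whole-cell sweeps from a binomial channel ensemble
#'
#' Per time point in the trace, the number of open channels is
#' `Binomial(n, Po(V))` with `Po` from the Boltzmann activation curve; the
#' macroscopic current is `open * gamma * (Vm - Vrev)` (pA, inward negative
#' below the reversal potential) plus Gaussian instrument noise. Before the
#' step the trace is baseline (noise only). Open counts are i.i.d. across
#' time points (stationary assumption); `correlated = TRUE` switches to a
#' two-state Markov gating scheme with the same stationary Po, for
#' robustness checks only.
#'
#' @param n_channels Channel count (>= 1).
#' @param gamma_ps Unitary conductance, pS (> 0).
#' @param v_half,k Boltzmann activation parameters, mV.
#' @param v_rev Reversal potential, mV.
#' @param voltages Step potentials, mV.
#' @param n_sweeps Repeats per voltage.
#' @param dt Sampling interval, ms.
#' @param baseline_ms,step_ms Pre-step baseline and step durations, ms.
#' @param sigma_instr Instrument noise SD, pA.
#' @param correlated Use the two-state Markov mode (mean open dwell
#'   `tau_open_ms`).
#' @param tau_open_ms Mean open dwell time for the Markov mode, ms.
#' @param seed Integer seed.
#' @return A [sweep_set()].
#' @export
simulate_sweeps <- function(n_channels = 12000, gamma_ps = 3.9, v_half = 5,
                            k = 8, v_rev = 70,
                            voltages = seq(-30, 40, by = 5), n_sweeps = 100,
                            dt = 1, baseline_ms = 10, step_ms = 150,
                            sigma_instr = 1, correlated = FALSE,
                            tau_open_ms = 2, seed = 1) {
  if (n_channels < 1 || gamma_ps <= 0) stop("need n_channels >= 1, gamma > 0")
  po <- boltzmann(voltages, v_half, k)
  if (any(po < 0 | po > 1)) stop("open probability outside [0, 1]")
  n_base <- round(baseline_ms / dt)
  n_step <- round(step_ms / dt) + 1
  with_local_seed(seed, {
    sweeps <- lapply(seq_along(voltages), function(vi) {
      drive <- (voltages[vi] - v_rev) * gamma_ps / 1000   # pA per open channel
      m <- matrix(0, n_base + n_step, n_sweeps)
      for (sw in seq_len(n_sweeps)) {
        open <- if (!correlated) {
          rbinom(n_step, n_channels, po[vi])
        } else {
          ## two-state Markov chain with stationary Po and open dwell tau
          p_close <- min(dt / tau_open_ms, 1)
          p_open <- min(p_close * po[vi] / (1 - po[vi]), 1)
          o <- numeric(n_step)
          o[1] <- rbinom(1, n_channels, po[vi])
          for (ti in 2:n_step)
            o[ti] <- o[ti - 1] +
              rbinom(1, n_channels - o[ti - 1], p_open) -
              rbinom(1, o[ti - 1], p_close)
          o
        }
        m[(n_base + 1):(n_base + n_step), sw] <- open * drive
      }
      m + rnorm(length(m), 0, sigma_instr)
    })
    sweep_set(sweeps, voltages, dt = dt, step_start = n_base * dt,
              step_end = (n_base + n_step - 1) * dt, v_rev = v_rev)
  })
}

#' Simulate an On gating-current transient with planted total charge
#'
#' Alpha-function transient `I(t) ~ t * exp(-t / tau)` scaled so its integral
#' over the step window equals `q_fc` exactly.
#'
#' @param q_fc Planted gating charge, fC.
#' @param tau_ms Transient time constant, ms.
#' @param dt Sampling interval, ms.
#' @param baseline_ms,step_ms Baseline and step durations, ms.
#' @param noise_pa Gaussian noise SD, pA.
#' @param seed Integer seed.
#' @return A [gating_record()].
#' @export
simulate_gating <- function(q_fc = 300, tau_ms = 1, dt = 0.01,
                            baseline_ms = 5, step_ms = 20, noise_pa = 0,
                            seed = 1) {
  n_base <- round(baseline_ms / dt)
  n_step <- round(step_ms / dt) + 1
  ts <- (seq_len(n_step) - 1) * dt
  ## truncated alpha-function integral: tau^2 (1 - e^{-T/tau} (1 + T/tau))
  tt <- step_ms / tau_ms
  denom <- tau_ms^2 * (1 - exp(-tt) * (1 + tt))
  amp <- q_fc / denom
  trace <- c(rep(0, n_base), amp * ts * exp(-ts / tau_ms))
  if (noise_pa > 0)
    trace <- with_local_seed(seed, trace + rnorm(length(trace), 0, noise_pa))
  gating_record(trace, dt = dt, baseline_start = 0,
                baseline_end = (n_base - 1) * dt, step_start = n_base * dt,
                step_end = (n_base + n_step - 1) * dt)
}

#' Generate a noisy two-state melting series
#'
#' Forward model is [melt_model()] (same temperature-unit convention as
#' [melt_fit()]) plus Gaussian noise on the CM.
#'
#' @param t_m Transition midpoint, degC.
#' @param delta_t Transition width.
#' @param alpha_n,beta_n,alpha_d,beta_d Baselines (in the working unit; the
#'   defaults put the native CM near 347 nm and the denatured CM near
#'   353 nm).
#' @param temperatures Scan temperatures, degC.
#' @param sigma_cm Noise SD on CM, nm.
#' @param kelvin Temperature-unit convention (must match the fit).
#' @param seed Integer seed.
#' @return data.frame `temperature`, `cm`, with generating parameters as
#'   attribute `truth`.
#' @export
make_melt_curves <- function(t_m = 55, delta_t = 5, alpha_n = 344.1,
                             beta_n = 0.01, alpha_d = 351.4, beta_d = 0.005,
                             temperatures = seq(20, 74, by = 2),
                             sigma_cm = 0.2, kelvin = TRUE, seed = 1) {
  off <- if (kelvin) 273.15 else 0
  cm <- melt_model(temperatures + off, t_m + off, delta_t, alpha_n, beta_n,
                   alpha_d, beta_d)
  if (sigma_cm > 0)
    cm <- with_local_seed(seed, cm + rnorm(length(cm), 0, sigma_cm))
  out <- data.frame(temperature = temperatures, cm = cm)
  attr(out, "truth") <- list(t_m = t_m, delta_t = delta_t, alpha_n = alpha_n,
                             beta_n = beta_n, alpha_d = alpha_d,
                             beta_d = beta_d, kelvin = kelvin)
  out
}

#' Generate a cosedimentation densitometry table
#'
#' Per replicate and condition, a total protein amount is drawn and split
#' into pellet and supernatant by the true bound fraction; both bands then
#' receive multiplicative log-normal densitometry noise.
#'
#' @param true_fractions Named numeric vector, true bound fraction per
#'   condition.
#' @param n_replicates Replicates per condition.
#' @param total_mean Mean total band intensity (arbitrary units).
#' @param noise_cv Log-normal coefficient of variation of band intensities.
#' @param seed Integer seed.
#' @return Lanes data.frame (`condition`, `replicate`, `supernatant`,
#'   `pellet`) for [bound_fraction()].
#' @export
make_densitometry <- function(true_fractions, n_replicates = 3,
                              total_mean = 1000, noise_cv = 0.1, seed = 1) {
  with_local_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rows <- list()
    for (cond in names(true_fractions)) {
      f <- true_fractions[[cond]]
      for (r in seq_len(n_replicates)) {
        total <- total_mean * rlnorm(1, -sdlog^2 / 2, sdlog)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, replicate = paste0("rep", r),
          supernatant = total * (1 - f) * rlnorm(1, -sdlog^2 / 2, sdlog),
          pellet = total * f * rlnorm(1, -sdlog^2 / 2, sdlog),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate a synthetic docking ensemble with known cluster structure
#'
#' Starting from the planted toy complex (with dummy backbone atoms), ligand
#' poses are drawn around `n_clusters` cluster centres (small rigid
#' perturbations within a cluster, large rotations/translations between
#' centres). Energies are assigned so that models closer to the planted pose
#' score better.
#'
#' @param seed Integer seed.
#' @param n_models Total number of models.
#' @param n_clusters Number of planted pose families.
#' @param spread Within-cluster rigid perturbation scale (Angstrom / ~deg).
#' @param separation Between-centre translation scale (Angstrom).
#' @param toy Optional toy complex from [make_toy_complex()] (built with
#'   `backbone = TRUE`); generated from `seed` when omitted.
#' @return List with `ensemble` (an [ensemble()]), `membership` (planted
#'   cluster index per model) and `toy`.
#' @export
make_toy_ensemble <- function(seed = 1, n_models = 10, n_clusters = 2,
                              spread = 0.5, separation = 25, toy = NULL) {
  if (is.null(toy))
    toy <- make_toy_complex(seed = seed, backbone = TRUE)
  base <- new_structure(rbind(toy$fixed, toy$scanning))
  lig_rows <- base$chain == "B"
  lig_xyz <- coord_matrix(new_structure(base[lig_rows, , drop = FALSE]))
  centroid <- colMeans(lig_xyz)
  rot_about <- function(axis, angle, pts, center) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
    sweep(sweep(pts, 2, center) %*% t(R), 2, center, "+")
  }
  with_local_seed(seed + 1, {
    ## cluster centres: first at the planted pose, others displaced/rotated
    centres <- lapply(seq_len(n_clusters), function(ci) {
      if (ci == 1) return(list(shift = c(0, 0, 0), axis = c(1, 0, 0),
                               angle = 0))
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ## push away from the fixed chain so displaced families stay clash-free
      dir <- dir + c(0, 2, 0); dir <- dir / sqrt(sum(dir^2))
      list(shift = separation * dir, axis = rnorm(3),
           angle = runif(1, pi / 4, pi / 2))
    })
    membership <- rep(seq_len(n_clusters), length.out = n_models)
    models <- lapply(seq_len(n_models), function(mi) {
      ce <- centres[[membership[mi]]]
      pts <- rot_about(ce$axis, ce$angle, lig_xyz, centroid)
      pts <- sweep(pts, 2, ce$shift, "+")
      ## small within-cluster rigid jitter
      pts <- rot_about(rnorm(3), rnorm(1, 0, spread * 0.02), pts,
                       colMeans(pts))
      pts <- sweep(pts, 2, rnorm(3, 0, spread), "+")
      s <- base
      s$x[lig_rows] <- pts[, 1]; s$y[lig_rows] <- pts[, 2]
      s$z[lig_rows] <- pts[, 3]
      displacement <- sqrt(mean(rowSums((pts - lig_xyz)^2)))
      en <- c(E_vdw = -40 + rnorm(1, 0, 2) + displacement,
              E_elec = -200 + rnorm(1, 0, 10) + 5 * displacement,
              E_desol = -10 + rnorm(1, 0, 1),
              E_air = 10 + 2 * displacement + rnorm(1, 0, 1))
      complex_model(new_structure(s), receptor_chains = c("A", "C"),
                    ligand_chain = "B", energies = en,
                    model_id = sprintf("model_%02d", mi))
    })
    list(ensemble = ensemble(models), membership = membership, toy = toy)
  })
}
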