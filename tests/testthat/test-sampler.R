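# Annealing schedule, proposals, moves, chain closure, Metropolis, run_mcmc.

test_that("annealing temperature follows the periodic cosine form", {
  sch <- anneal_schedule()
  expect_equal(temperature_at(0, sch), 600)
  expect_equal(temperature_at(sch$omega / 2, sch), 0, tolerance = 1e-9)
  k <- c(0, 17, 123, 4999)
  expect_equal(temperature_at(k + sch$omega, sch), temperature_at(k, sch))
  expect_true(all(temperature_at(0:10000, sch) >= 0))
  sch2 <- anneal_schedule(amplitude = 400, shift = 50)
  expect_equal(max(temperature_at(0:5000, sch2)), 450)
  expect_equal(min(temperature_at(0:5000, sch2)), 50, tolerance = 1e-6)
  expect_error(anneal_schedule(amplitude = -1), "amplitude")
  expect_error(anneal_schedule(omega = 1), "omega")
})

test_that("metropolis rule accepts downhill, quenches at T=0, has exp(-dE) rate", {
  expect_true(metropolis_accept(-1, 0))
  expect_true(metropolis_accept(-1, 1e5))
  expect_false(metropolis_accept(5, 0))
  set.seed(1)
  n <- 1e5
  acc <- vapply(seq_len(n), function(i) metropolis_accept(1, 300), logical(1))
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(acc) - p), 3 * se)
})

test_that("proposals are symmetric, bounded and deterministic given the seed", {
  cx <- make_toy_complex(toy_spec())
  set.seed(5)
  p1 <- propose_region_move(cx$structure, cx$hierarchy, 2)
  set.seed(5)
  p2 <- propose_region_move(cx$structure, cx$hierarchy, 2)
  expect_identical(p1, p2)
  # amplitude zero -> identity proposal
  h0 <- cx$hierarchy
  h0$nodes[[2]]$max_trans <- 0; h0$nodes[[2]]$max_rot <- 0
  p0 <- propose_region_move(cx$structure, h0, 2)
  expect_equal(p0$translation, c(0, 0, 0))
  expect_equal(p0$angle, 0)
  # pivot is the centroid of the node's CA beads
  nd <- cx$structure[cx$structure$chain == "M" & cx$structure$resno <= 12 &
                       cx$structure$kind == "CA", ]
  expect_equal(p1$pivot, unname(colMeans(as.matrix(nd[, c("x", "y", "z")]))),
               tolerance = 1e-12)
  # CLT: translation components average to ~0, bounded by t_max
  set.seed(9)
  tr <- t(replicate(5000, propose_region_move(cx$structure, cx$hierarchy, 2)$translation))
  tmax <- cx$hierarchy$nodes[[2]]$max_trans
  expect_true(all(abs(tr) <= tmax))
  se <- tmax / sqrt(3) / sqrt(nrow(tr))
  expect_true(all(abs(colMeans(tr)) < 3 * se))
})

test_that("apply_move is a rigid isometry of the node and identity elsewhere", {
  cx <- make_toy_complex(toy_spec())
  st <- cx$structure
  set.seed(3)
  pr <- propose_region_move(st, cx$hierarchy, 5)
  st2 <- apply_move(st, pr)
  idx <- pr$idx
  d0 <- dist(bead_coords(st)[idx, ])
  d1 <- dist(bead_coords(st2)[idx, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  expect_equal(bead_coords(st2)[-idx, ], bead_coords(st)[-idx, ])
  # identity proposal leaves the structure unchanged
  pr0 <- pr; pr0$translation <- c(0, 0, 0); pr0$angle <- 0
  expect_equal(bead_coords(apply_move(st, pr0)), bead_coords(st))
  # pure translation shifts every node bead by exactly that vector
  prt <- pr; prt$angle <- 0; prt$translation <- c(0.1, 0, 0)
  st3 <- apply_move(st, prt)
  expect_equal(bead_coords(st3)[idx, ],
               sweep(bead_coords(st)[idx, ], 2, c(0.1, 0, 0), "+"),
               tolerance = 1e-12)
})

test_that("chain closure restores broken virtual bonds within tolerance", {
  cx <- make_toy_complex(toy_spec())
  st <- cx$structure
  # whole-peptide move: no breaks, structure unchanged by closure
  pr <- propose_region_move(st, cx$hierarchy, 8)
  st2 <- apply_move(st, pr)
  cl <- close_chain(st2, cx$hierarchy, 8, ref = st)
  expect_true(cl$converged)
  expect_length(cl$residuals, 0)
  expect_equal(bead_coords(cl$structure), bead_coords(st2))
  # artificial 0.05 nm gap at the helix1_c boundary: residual <= 0.02 nm
  nrt <- hnmmc:::node_runtime(st, cx$hierarchy, 3L)[[4]]
  co <- bead_coords(st)
  co[nrt$idx, 3] <- co[nrt$idx, 3] + 0.05
  stg <- set_bead_coords(st, co)
  cl2 <- close_chain(stg, cx$hierarchy, 4, ref = st)
  expect_true(cl2$converged)
  expect_true(all(cl2$residuals <= 0.02))
  # only node + closure-zone beads may differ from the gapped structure
  moved <- which(rowSums(abs(bead_coords(cl2$structure) - bead_coords(stg))) > 1e-12)
  expect_true(all(moved %in% nrt$affected))
  # unreachable gap (far larger than the zone can span) fails gracefully
  co2 <- bead_coords(st)
  co2[nrt$idx, 3] <- co2[nrt$idx, 3] + 5
  clf <- close_chain(set_bead_coords(st, co2), cx$hierarchy, 4, ref = st)
  expect_false(clf$converged)
})

test_that("run_mcmc honours trivial contracts and is bit-reproducible", {
  cx <- make_toy_complex(toy_spec())
  go <- make_go_potential(cx)
  # zero steps: only the initial snapshot
  tr0 <- run_mcmc(go$structure, cx$hierarchy, go$potential,
                  anneal_schedule(total_steps = 0), seed = 1,
                  probes = cx$probes, snapshot_stride = 10)
  expect_equal(dim(tr0$snapshots)[1], 1)
  expect_equal(tr0$snap_steps, 0L)
  # zero amplitudes everywhere: constant energy trace
  h0 <- cx$hierarchy
  for (i in seq_along(h0$nodes)) {
    h0$nodes[[i]]$max_trans <- 0; h0$nodes[[i]]$max_rot <- 0
  }
  trz <- run_mcmc(go$structure, h0, go$potential,
                  anneal_schedule(total_steps = 300), seed = 1)
  expect_equal(length(unique(round(trz$energy, 9))), 1)
  # determinism: same seed twice gives identical runs
  sch <- anneal_schedule(total_steps = 500)
  tra <- run_mcmc(go$structure, cx$hierarchy, go$potential, sch, seed = 11,
                  probes = cx$probes)
  trb <- run_mcmc(go$structure, cx$hierarchy, go$potential, sch, seed = 11,
                  probes = cx$probes)
  expect_identical(tra$energy, trb$energy)
  expect_identical(bead_coords(tra$final_structure), bead_coords(trb$final_structure))
  # the emitted temperature trace reproduces temperature_at exactly
  expect_equal(tra$temperature, temperature_at(0:(sch$total_steps - 1), sch))
  # chain integrity: consecutive CA-CA distances stay in the sanity band
  fin <- tra$final_structure
  for (ch in c("M", "P")) {
    ca <- bead_coords(fin)[fin$kind == "CA" & fin$chain == ch, ]
    d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
    expect_true(all(d > 0.2 & d < 0.6))
  }
})

test_that("replicas are seeded independently and reproducibly", {
  cx <- make_toy_complex(toy_spec())
  go <- make_go_potential(cx)
  sch <- anneal_schedule(total_steps = 400)
  # n = 1 equals a single run with seed base + 1
  r1 <- run_replicas(go$structure, cx$hierarchy, go$potential, cx$probes,
                     sch, n_replicas = 1, base_seed = 7, probe_stride = 50)
  single <- run_mcmc(go$structure, cx$hierarchy, go$potential, sch, seed = 8,
                     probes = cx$probes, probe_stride = 50,
                     store_snapshots = FALSE)
  expect_equal(r1$distances[1, , ], pmin(single$probe_track, 3.0),
               ignore_attr = TRUE)
  # same base seed twice: bit-identical; different replicas differ
  r2 <- run_replicas(go$structure, cx$hierarchy, go$potential, cx$probes,
                     sch, n_replicas = 2, base_seed = 7, probe_stride = 50)
  expect_identical(r2$distances[1, , ], r1$distances[1, , ])
  expect_false(identical(r2$distances[1, , ], r2$distances[2, , ]))
})
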