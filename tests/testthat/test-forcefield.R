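# Pair potential: scaling function, lookups, full and incremental sums.

test_that("scaling function matches its closed form and is continuous", {
  p <- scaling_params()
  expect_identical(scale_factor(0, p), 0.15)
  expect_identical(scale_factor(0.7, p), 1.0)
  expect_identical(scale_factor(1.2, p), 1.0)
  expect_equal(scale_factor(0.35, p), 0.16328125, tolerance = 1e-15)
  # continuity at r0 and monotonicity below it
  eps <- 10^-(4:9)
  expect_true(all(abs(scale_factor(0.7 - eps, p) - 1) < 1e-3))
  expect_equal(scale_factor(0.7 - 1e-9, p), 1, tolerance = 1e-8)
  r <- seq(0, 0.7, length.out = 200)
  expect_true(all(diff(scale_factor(r, p)) >= 0))
  expect_error(scale_factor(-0.1, p), "negative")
  # parameter validation
  expect_error(scaling_params(s0 = 0), "s0")
  expect_error(scaling_params(r0 = -1), "r0")
})

test_that("pair_energy applies bins, cutoff, scaling and exclusions", {
  types <- c("CA", "SC_A")
  E <- array(0, c(2, 2, 30))
  E[2, 2, ] <- -2.0   # SC_A/SC_A attractive in every bin
  pot <- pair_potential(types, E, bin_width = 0.05, cutoff = 1.5)
  expect_equal(pair_energy(1.5, "SC_A", "SC_A", pot), 0)    # at cutoff
  expect_equal(pair_energy(2.0, "SC_A", "SC_A", pot), 0)    # beyond
  expect_equal(pair_energy(1.0, "SC_A", "SC_A", pot), -2.0) # s(r)=1 regime
  expect_equal(pair_energy(0.35, "SC_A", "SC_A", pot), -0.3265625,
               tolerance = 1e-12)
  expect_equal(pair_energy(0.5, "SC_A", "SC_A", pot, seq_sep = 2), 0)
  expect_equal(pair_energy(0.5, "CA", "SC_A", pot), 0)
  expect_error(pair_energy(0.5, "SC_Q", "SC_A", pot), "unknown bead type")
  # table validation
  E2 <- E; E2[1, 2, 3] <- 1
  expect_error(pair_potential(types, E2), "symmetric")
  expect_error(pair_potential(types, E, bin_width = 0.05, cutoff = 1.4),
               "cutoff")
})

test_that("total energy equals the independent R double-loop oracle", {
  pot <- random_potential(seed = 11)
  set.seed(42)
  for (rep in 1:3) {
    st <- tiny_beads(5, 2)
    st <- set_bead_coords(st, bead_coords(st) + matrix(rnorm(nrow(st) * 3, 0, 0.05),
                                                       ncol = 3))
    eb <- total_energy(st, pot, peptide_chain = "B")
    expect_equal(eb$total, r_total_energy(st, pot), tolerance = 1e-9)
    expect_equal(eb$total,
                 eb$peptide_receptor + eb$intra_receptor + eb$intra_peptide,
                 tolerance = 1e-9)
  }
  # trivial cases: single pair beyond r0 scores the raw table value
  df <- data.frame(chain = c("A", "A", "B", "B"), resno = c(1, 1, 1, 1),
                   res = "A", kind = c("CA", "O", "CA", "O"),
                   x = c(0, 0, 1.0, 1.0), y = c(0, 0.24, 0, 0.24), z = 0)
  st2 <- bead_structure(df)
  types <- c("CA", "O")
  E <- array(0, c(2, 2, 30)); E[1, 1, ] <- -1.5
  pot2 <- pair_potential(types, E)
  # CA-CA at exactly 1.0 nm (>= r0): raw value; O beads inert
  expect_equal(total_energy(st2, pot2)$total, -1.5 + 0 +
                 pair_energy(sqrt(1 + 0.24^2), "CA", "O", pot2) * 2,
               tolerance = 1e-9)
})

test_that("energy is invariant under global rigid isometries", {
  cx <- make_toy_complex(toy_spec())
  go <- make_go_potential(cx)
  e0 <- total_energy(go$structure, go$potential)$total
  set.seed(7)
  for (rep in 1:5) {
    q <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(q))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tr <- rnorm(3)
    co <- bead_coords(go$structure) %*% R + matrix(tr, nrow(go$structure), 3, byrow = TRUE)
    e1 <- total_energy(set_bead_coords(go$structure, co), go$potential)$total
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("delta energy equals the full recompute for region moves", {
  cx <- make_toy_complex(toy_spec())
  go <- make_go_potential(cx)
  st <- go$structure
  e_full0 <- total_energy(st, go$potential)$total
  # null move
  expect_equal(delta_energy(st, 1:6, bead_coords(st)[1:6, ], go$potential), 0)
  # single-bead displacement in a 3-bead slice: hand-summed affected pairs
  df <- data.frame(chain = c("A", "A", "B", "B", "C", "C"),
                   resno = 1, res = "A",
                   kind = rep(c("CA", "O"), 3),
                   x = c(0, 0, 0.8, 0.8, 1.6, 1.6),
                   y = rep(c(0, 0.24), 3), z = 0)
  st3 <- bead_structure(df)
  types <- c("CA", "O"); E <- array(0, c(2, 2, 40)); E[1, 1, ] <- -1
  pot3 <- pair_potential(types, E, bin_width = 0.05, cutoff = 2.0)
  co <- bead_coords(st3); old <- co[3, , drop = FALSE]
  co[3, 1] <- 0.55   # inside the scaled short-range regime on one side
  st3b <- set_bead_coords(st3, co)
  hand <- (pair_energy(0.55, "CA", "CA", pot3) + pair_energy(1.05, "CA", "CA", pot3)) -
          2 * pair_energy(0.8, "CA", "CA", pot3)
  expect_equal(delta_energy(st3b, 3L, old, pot3), hand, tolerance = 1e-12)
  # length mismatch is rejected
  expect_error(delta_energy(st3b, c(3L, 4L), old, pot3), "rows")
  # random region moves on the toy complex match the full recompute
  set.seed(21)
  nrt <- hnmmc:::node_runtime(st, cx$hierarchy, 3L)
  for (rep in 1:25) {
    node <- sample(length(cx$hierarchy$nodes), 1)
    pr <- propose_region_move(st, cx$hierarchy, node)
    st2 <- apply_move(st, pr)
    cl <- close_chain(st2, cx$hierarchy, node, ref = st)
    if (!cl$converged) next
    aff <- nrt[[node]]$affected
    dE <- delta_energy(cl$structure, aff, bead_coords(st)[aff, , drop = FALSE],
                       go$potential)
    expect_equal(dE, total_energy(cl$structure, go$potential)$total - e_full0,
                 tolerance = 1e-6 * max(1, abs(e_full0)))
  }
})

test_that("potential tables round-trip bit-exactly through their file format", {
  pot <- random_potential(seed = 3)
  f <- tempfile(fileext = ".txt")
  write_pair_potential(pot, f)
  pot2 <- read_pair_potential(f)
  expect_identical(pot2$types, pot$types)
  expect_identical(pot2$energies, pot$energies)
  expect_identical(pot2$bin_width, pot$bin_width)
  expect_identical(pot2$cutoff, pot$cutoff)
  expect_identical(pot2$min_seq_sep, pot$min_seq_sep)
  expect_identical(pot2$typing, pot$typing)
})

test_that("the default potential is symmetric, repulsive-cored and loadable", {
  pot <- default_pair_potential()
  expect_true(all(pot$energies[, , 1:4] >= 0))
  expect_equal(pot$cutoff, pot$bin_width * dim(pot$energies)[3])
  st <- tiny_beads(4, 2)
  expect_silent(total_energy(st, pot))
})
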