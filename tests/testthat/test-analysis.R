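# Probe distances, clamping, summaries, pathway classes, AROC, bootstrap.

test_that("probe distances are plain CA-CA Euclidean distances", {
  df <- data.frame(chain = c("M", "M", "P", "P"), resno = 1, res = "A",
                   kind = rep(c("CA", "O"), 2),
                   x = c(0, 0, 0.3, 0.3), y = c(0, 0.24, 0.4, 0.64),
                   z = 0)
  st <- bead_structure(df)
  pr <- probe_set("P", "M", c(1, 1, 1), c(1, 1, 1))
  d <- probe_distances(st, pr)
  expect_equal(unname(d), rep(0.5, 3))   # 3-4-5 triangle
  expect_named(d, c("N", "mid", "C"))
  # coincident pair -> 0
  df0 <- df; df0[3, c("x", "y")] <- df0[1, c("x", "y")]
  expect_equal(unname(probe_distances(bead_structure(df0, check = FALSE), pr)[1]), 0)
  # missing residue is an error
  expect_error(probe_distances(st, probe_set("P", "M", c(1, 2, 1), c(1, 1, 1))),
               "not found")
  # toy complex: bent pose, middle probe starts largest
  cx <- make_toy_complex(toy_spec())
  d3 <- probe_distances(cx$structure, cx$probes)
  expect_gt(d3["mid"], d3["N"])
  expect_gt(d3["mid"], d3["C"])
})

test_that("clamping maps distances above the ceiling to exactly the ceiling", {
  expect_identical(clamp_distance(3.5), 3.0)
  expect_identical(clamp_distance(2.9), 2.9)
  expect_identical(clamp_distance(3.0), 3.0)
  expect_equal(clamp_distance(c(0, 2, 5), ceiling = 3), c(0, 2, 3))
  expect_error(clamp_distance(-1), "negative")
})

test_that("mean/SEM curves follow the textbook formulas", {
  d <- array(1, c(2, 3, 3)); d[2, , ] <- 2
  ms <- mean_sem_curves(rs_from_array(d))
  expect_equal(unique(ms$mean), 1.5)
  expect_equal(unique(ms$sem), 0.5)   # sd(c(1,2))/sqrt(2)
  # identical replicas -> SEM 0
  d2 <- array(1.3, c(3, 4, 3))
  expect_true(all(mean_sem_curves(rs_from_array(d2))$sem == 0))
  # single replica: mean equals the trajectory, SEM missing
  d1 <- array(seq_len(12) / 10, c(1, 4, 3))
  ms1 <- mean_sem_curves(rs_from_array(d1))
  expect_equal(ms1$mean, as.vector(d1[1, , ]))
  expect_true(all(is.na(ms1$sem)))
})

test_that("detachment score is the mean clamped probe distance", {
  d <- array(0, c(1, 1, 3)); d[1, 1, ] <- c(1, 2, 3)
  expect_equal(detachment_score(rs_from_array(d)), 2)
  dc <- array(3, c(4, 5, 3))
  expect_equal(detachment_score(rs_from_array(dc)), 3)
  # uniformly shifting all (pre-clamp, below ceiling) distances raises it
  set.seed(1)
  d3 <- array(runif(2 * 10 * 3, 0.5, 2.0), c(2, 10, 3))
  expect_gt(detachment_score(rs_from_array(d3 + 0.3)),
            detachment_score(rs_from_array(d3)))
  # probe subset and tail window options
  expect_equal(detachment_score(rs_from_array(d), probes = "C"), 3)
})

test_that("pathway classification follows the detachment-time rules", {
  expect_equal(as.character(classify_pathway(trajectory_with_times(Inf, Inf, Inf))),
               "stable")
  expect_equal(as.character(classify_pathway(trajectory_with_times(500, 600, 100))),
               "C-first")
  expect_equal(as.character(classify_pathway(trajectory_with_times(100, 600, 500))),
               "N-first")
  expect_equal(as.character(classify_pathway(trajectory_with_times(200, 400, 200))),
               "simultaneous-ends")
  expect_equal(as.character(classify_pathway(trajectory_with_times(150, 20, 150))),
               "middle-first")
  # an end leading within the tie margin is simultaneous
  expect_equal(as.character(classify_pathway(trajectory_with_times(100, 150, 103))),
               "simultaneous-ends")
  # persistence: a short spike below the window length does not count
  d <- array(1, c(1, 100, 3))
  d[1, 20:24, 3] <- 2.6            # 5-snapshot spike on C
  d[1, 60:100, 1] <- 2.6           # sustained N detachment
  expect_equal(as.character(classify_pathway(rs_from_array(d), window = 10)),
               "N-first")
})

test_that("auroc matches brute-force pair enumeration and its symmetry law", {
  expect_equal(auroc(c(3, 1, 2, 0.5), c("non-binder", "non-binder", "binder", "binder")),
               0.75)
  expect_equal(auroc(c(5, 6), c("binder", "non-binder")), 1.0)
  expect_equal(auroc(c(2, 2, 2), c("binder", "non-binder", "binder")), 0.5)
  expect_error(auroc(1:3, rep("binder", 3)), "both")
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    labels <- sample(c("binder", "non-binder"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    a <- auroc(scores, labels)
    expect_equal(a, bruteforce_auroc(scores, labels), tolerance = 1e-12)
    if (!any(duplicated(scores)))
      expect_equal(a + auroc(-scores, labels), 1, tolerance = 1e-12)
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(60)
  labels <- sample(c("binder", "non-binder"), 60, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("binder", "non-binder"),
    direction = "<", quiet = TRUE)))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("pearson correlation handles transforms and degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x + 1, transform = identity), 1.0)
  expect_equal(pearson_r(x, -x + 10, transform = identity), -1.0)
  expect_equal(pearson_r(x, c(1, 3, 2), transform = identity), 0.5)
  expect_equal(pearson_r(x, 10^x), 1.0)   # default log10 linearises
  expect_error(pearson_r(x, c(2, 2, 2), transform = identity), "constant")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "3 points")
})

test_that("bootstrap AROC SD shrinks with the replica count", {
  # identical replicas: no resampling variance at any n
  scores0 <- matrix(rep(c(1, 1, 2, 2), each = 10), 4, 10, byrow = TRUE)
  labels <- c("binder", "binder", "non-binder", "non-binder")
  bs0 <- bootstrap_auroc_sd(scores0, labels, n_values = c(1, 5, 10), B = 50, seed = 1)
  expect_equal(bs0$sd_auroc, c(0, 0, 0))
  # determinism
  set.seed(2)
  scores <- matrix(rnorm(8 * 100, mean = rep(c(1, 2), each = 4)), 8, 100)
  labs <- rep(c("binder", "non-binder"), each = 4)
  b1 <- bootstrap_auroc_sd(scores, labs, n_values = c(1, 25, 100), B = 200, seed = 9)
  b2 <- bootstrap_auroc_sd(scores, labs, n_values = c(1, 25, 100), B = 200, seed = 9)
  expect_identical(b1, b2)
  # strict SD decrease across n = 1, 25, 100 for noisy replica scores
  expect_true(all(diff(b1$sd_auroc) < 0))
  expect_error(bootstrap_auroc_sd(scores, labs, n_values = 200, B = 10, seed = 1),
               "n_values")
  expect_error(bootstrap_auroc_sd(scores, rep("binder", 8), B = 10, seed = 1),
               "both")
})

test_that("binding records validate class/IC50 consistency", {
  br <- binding_records(c("AAA", "BBB"), ic50 = c(100, 5000))
  expect_equal(br$class, c("binder", "non-binder"))
  expect_error(binding_records("AAA", class = "non-binder", ic50 = 100),
               "inconsistent")
  expect_error(binding_records("AAA", class = "maybe"), "class")
  expect_error(binding_records("AAA"), "class labels or IC50")
})
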