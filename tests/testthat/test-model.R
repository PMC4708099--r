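# Coarse-graining, threading and the pMHC region hierarchy.

test_that("coarse-graining places beads per the 3-point rules", {
  lines <- c(
    # ALA: SC centroid = CB exactly
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line(3, "C", "ALA", "A", 1, 3.0, 0, 0),
    pdb_line(4, "O", "ALA", "A", 1, 3.0, 1.2, 0),
    pdb_line(5, "CB", "ALA", "A", 1, 1.5, -1.5, 0),
    # GLY: no SC bead
    pdb_line(6, "N", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(7, "CA", "GLY", "A", 2, 5.3, 0.7, 0),
    pdb_line(8, "C", "GLY", "A", 2, 6.8, 0, 0),
    pdb_line(9, "O", "GLY", "A", 2, 6.8, -1.2, 0),
    # LEU: 4-atom centroid, hand-computed (0.75, 0, 0) A beyond CA offset
    pdb_line(10, "N", "LEU", "A", 3, 7.6, 0, 0),
    pdb_line(11, "CA", "LEU", "A", 3, 9.1, 0.7, 0),
    pdb_line(12, "C", "LEU", "A", 3, 10.6, 0, 0),
    pdb_line(13, "O", "LEU", "A", 3, 10.6, 1.2, 0),
    pdb_line(14, "CB", "LEU", "A", 3, 0, 0, 0),
    pdb_line(15, "CG", "LEU", "A", 3, 1, 0, 0),
    pdb_line(16, "CD1", "LEU", "A", 3, 1, 1, 0),
    pdb_line(17, "CD2", "LEU", "A", 3, 1, -1, 0))
  st <- coarse_grain_structure(write_test_pdb(lines))
  expect_s3_class(st, "bead_structure")
  a1 <- st[st$resno == 1, ]
  expect_equal(a1$x[a1$kind == "CA"], 0.15)                 # A -> nm
  expect_equal(unlist(a1[a1$kind == "SC", c("x", "y", "z")]),
               c(x = 0.15, y = -0.15, z = 0), tolerance = 1e-12)
  expect_false("SC" %in% st$kind[st$resno == 2])            # glycine rule
  l3 <- st[st$resno == 3 & st$kind == "SC", ]
  expect_equal(unlist(l3[, c("x", "y", "z")]),
               c(x = 0.075, y = 0, z = 0), tolerance = 1e-12)
})

test_that("coarse-graining resolves altlocs by occupancy and errors on missing backbone", {
  lines <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, alt = "A", occ = 0.3),
    pdb_line(2, "CA", "ALA", "A", 1, 2.0, 0, 0, alt = "B", occ = 0.7),
    pdb_line(3, "O", "ALA", "A", 1, 2.0, 2.4, 0),
    pdb_line(4, "CB", "ALA", "A", 1, 2.0, -1.5, 0))
  expect_message(st <- coarse_grain_structure(write_test_pdb(lines)),
                 "alternate location")
  expect_equal(st$x[st$kind == "CA"], 0.2)  # highest-occupancy copy kept
  # residue without carbonyl O is a hard error naming the residue
  bad <- c(pdb_line(1, "CA", "ALA", "A", 7, 1.0, 0, 0),
           pdb_line(2, "CB", "ALA", "A", 7, 1.0, -1.5, 0))
  expect_error(coarse_grain_structure(write_test_pdb(bad)), "chain A residue 7")
})

test_that("re-centroiding a 3-point model is the identity", {
  # a bead structure written as pseudo-atom PDB and re-coarse-grained keeps
  # CA and O and treats the SC pseudo-atom as the (single-atom) centroid
  st <- tiny_beads(4, 0)
  f <- tempfile(fileext = ".pdb")
  write_beads_pdb(st, f)
  st2 <- coarse_grain_structure(f)
  expect_equal(bead_coords(st2), bead_coords(st), tolerance = 1e-3)
})

test_that("threading swaps side chains but never touches the backbone", {
  st <- tiny_beads(6, 3)
  same <- thread_peptide(st, "B", "AAA")
  expect_equal(as.data.frame(same), as.data.frame(st))
  # A -> G drops the SC bead, everything else identical
  g2 <- thread_peptide(st, "B", "AGA")
  expect_false(any(g2$kind == "SC" & g2$chain == "B" & g2$resno == 2))
  keep <- !(st$chain == "B" & st$resno == 2 & st$kind == "SC")
  expect_equal(bead_coords(g2), bead_coords(st)[keep, , drop = FALSE])
  # A -> W repositions SC at the canonical W distance along the old direction
  w2 <- thread_peptide(st, "B", "AWA")
  ca <- unlist(w2[w2$chain == "B" & w2$resno == 2 & w2$kind == "CA", c("x", "y", "z")])
  sc <- unlist(w2[w2$chain == "B" & w2$resno == 2 & w2$kind == "SC", c("x", "y", "z")])
  expect_equal(sqrt(sum((sc - ca)^2)), unname(hnmmc:::CA_SC_DIST[["W"]]),
               tolerance = 1e-9)
  sc_old <- unlist(st[st$chain == "B" & st$resno == 2 & st$kind == "SC", c("x", "y", "z")])
  u_old <- (sc_old - ca) / sqrt(sum((sc_old - ca)^2))
  u_new <- (sc - ca) / sqrt(sum((sc - ca)^2))
  expect_equal(u_new, u_old, tolerance = 1e-9)
  # receptor chain untouched in all cases
  expect_equal(as.data.frame(w2[w2$chain == "A", ]),
               as.data.frame(st[st$chain == "A", ]))
  # errors: length mismatch names both lengths; unknown code rejected
  expect_error(thread_peptide(st, "B", "AAAA"), "4.*3|3.*4")
  expect_error(thread_peptide(st, "B", "AZA"), "unknown residue")
})

test_that("default pMHC decomposition yields 7 MHC nodes and a valid tree", {
  cx <- make_toy_complex(toy_spec())
  h <- cx$hierarchy
  expect_equal(chain_node_count(h, "M"), 7)
  # peptide: 3 leaves partitioning 1..9 under one super-region
  pep_nodes <- which(vapply(h$nodes, function(n) n$chain == "P", logical(1)))
  leaves <- pep_nodes[!is.na(vapply(h$nodes[pep_nodes], `[[`, integer(1), "parent"))]
  expect_length(leaves, 3)
  expect_equal(sort(unlist(lapply(leaves, node_residues, h = h))), 1:9)
  super <- setdiff(pep_nodes, leaves)
  expect_equal(node_residues(h, super), 1:9)
  # union of leaf residues under each super-region equals the super's set
  for (p in seq_along(h$nodes)) {
    kids <- which(vapply(h$nodes, function(n) !is.na(n$parent) && n$parent == p,
                         logical(1)))
    if (length(kids))
      expect_equal(sort(unlist(lapply(kids, node_residues, h = h))),
                   node_residues(h, p))
  }
})

test_that("degenerate hierarchy configs are rejected", {
  cx <- make_toy_complex(toy_spec())
  cfg <- list(mhc_chain = "M", peptide_chain = "P",
              helix1_range = c(1L, 12L), helix1_kink = 1L,   # empty sub-region
              helix2_range = c(27L, 38L), helix2_kink = 33L)
  expect_error(build_pmhc_hierarchy(cx$structure, cfg), "kink")
  cfg$helix1_kink <- 20L                                     # outside helix
  expect_error(build_pmhc_hierarchy(cx$structure, cfg), "kink")
  cfg$helix1_kink <- 7L
  cfg$helix2_range <- c(10L, 30L)                            # overlaps helix1
  expect_error(build_pmhc_hierarchy(cx$structure, cfg), "overlap")
})

test_that("bead-structure invariants are enforced", {
  df <- as.data.frame(tiny_beads(4, 0))
  # broken virtual bond
  df2 <- df; df2$x[df2$resno == 4] <- df2$x[df2$resno == 4] + 5
  expect_error(bead_structure(df2), "CA-CA")
  # glycine with SC bead
  df3 <- df; df3$res[1:3] <- "G"
  expect_error(bead_structure(df3), "glycine")
  # duplicated CA
  df4 <- rbind(df, df[df$kind == "CA" & df$resno == 1, ])
  df4 <- df4[order(df4$resno), ]
  expect_error(bead_structure(df4), "exactly one")
})
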