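# Shared fixtures and independent reference implementations.

# --- tiny hand-built bead structures --------------------------------------

# a straight two-chain system: receptor chain "A" (n residues along x),
# peptide chain "B" (m residues above it); pleated so closure has leverage
tiny_beads <- function(n = 6, m = 3, spacing = 0.38) {
  mk <- function(chain, i, z0) {
    ca <- c((i - 1) * spacing, 0.07 * (-1)^i, z0)
    data.frame(chain = chain, resno = i, res = "A",
               kind = c("CA", "O", "SC"),
               x = ca[1] + c(0, 0.0, 0.0),
               y = ca[2] + c(0, 0.17, -0.22),
               z = ca[3] + c(0, 0.17, 0.22),
               stringsAsFactors = FALSE)
  }
  df <- rbind(do.call(rbind, lapply(seq_len(n), mk, chain = "A", z0 = 0)),
              if (m > 0) do.call(rbind, lapply(seq_len(m), mk, chain = "B", z0 = 0.8)))
  bead_structure(df)
}

# independent all-pairs energy sum in plain R (oracle for the C++ kernel)
r_total_energy <- function(structure, pot, params = scaling_params()) {
  co <- bead_coords(structure)
  types <- if (pot$typing == "column") structure$type else default_bead_types(structure)
  ti <- match(types, pot$types)
  meta <- hnmmc:::bead_meta(structure)
  nb <- dim(pot$energies)[3]
  tot <- 0
  n <- nrow(co)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (meta$chain[i] == meta$chain[j] &&
        abs(meta$ord[i] - meta$ord[j]) < pot$min_seq_sep) next
    r <- sqrt(sum((co[i, ] - co[j, ])^2))
    if (r >= pot$cutoff) next
    bin <- floor(r / pot$bin_width) + 1
    if (bin > nb) next
    e <- pot$energies[ti[i], ti[j], bin]
    s <- if (r < params$r0) params$s0 + (1 - params$s0) * (r / params$r0)^6 else 1
    tot <- tot + e * s
  }
  tot
}

# brute-force AROC: enumerate all (non-binder, binder) pairs, ties = 1/2
bruteforce_auroc <- function(scores, labels) {
  pos <- scores[labels == "non-binder"]
  neg <- scores[labels == "binder"]
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# random small pair potential over the default typing vocabulary
random_potential <- function(seed = 1, nb = 30, bin_width = 0.05) {
  set.seed(seed)
  types <- c("CA", "O", paste0("SC_", setdiff(hnmmc:::AA1, "G")))
  nt <- length(types)
  E <- array(0, c(nt, nt, nb))
  for (b in seq_len(nb)) {
    m <- matrix(stats::rnorm(nt * nt, 0, 0.5), nt, nt)
    E[, , b] <- (m + t(m)) / 2
  }
  pair_potential(types, E, bin_width = bin_width)
}

# replica set built directly from a distance array
rs_from_array <- function(d, steps = seq_len(dim(d)[2]), ceiling = 3.0) {
  dimnames(d)[[3]] <- c("N", "mid", "C")
  replica_set("test", NA_character_, steps, d, ceiling = ceiling)
}

# a synthetic single-replica trajectory with prescribed per-probe
# detachment times (snapshot at which the probe jumps above 2.5 and stays)
trajectory_with_times <- function(tN, tM, tC, n_steps = NULL, base = 1.0) {
  tt0 <- c(tN, tM, tC)
  if (is.null(n_steps)) n_steps <- max(200, tt0[is.finite(tt0)] + 50)
  d <- array(base, c(1, n_steps, 3))
  tt <- c(tN, tM, tC)
  for (p in 1:3) if (is.finite(tt[p])) d[1, tt[p]:n_steps, p] <- 2.5
  rs_from_array(d)
}

# PDB text builder for parser tests (fixed-format ATOM records)
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                    alt = " ", occ = 1.0) {
  sprintf("ATOM  %5d %-4s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0)
}

write_test_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# small toy detachment experiment shared by sampler/analysis tests
run_toy_replicas <- function(spec, n_replicas, steps, base_seed,
                             probe_stride = 100) {
  cx <- make_toy_complex(spec)
  go <- make_go_potential(cx)
  sch <- anneal_schedule(total_steps = steps)
  run_replicas(go$structure, cx$hierarchy, go$potential, cx$probes, sch,
               n_replicas = n_replicas, base_seed = base_seed,
               probe_stride = probe_stride)
}
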