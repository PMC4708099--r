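#' Specification of a toy groove-peptide complex
#'
#' Desk-scale stand-in for a class I MHC binding groove: two parallel
#' helix rails above a beta-floor strip, all one receptor chain (rail -
#' linker - floor - linker - rail), with a peptide laid along the groove in
#' a slightly bent pose whose ends sit about 0.2 nm closer to the floor
#' than its middle, as in crystallographic pMHC poses. Anchor positions
#' default to peptide positions 2 and the C-terminal residue of a 9-mer,
#' mirroring the HLA-A*02:01 anchor concept.
#'
#' @param groove_length residues per helix rail
#' @param floor_width residues of the floor strip
#' @param peptide_length peptide residues (>= 3)
#' @param spacing CA-CA virtual bond length, nm
#' @param anchor_positions peptide positions treated as anchors
#' @param anchor_depth Go well depth at anchor contacts, k_B*T_ref (<= 0)
#' @param background_depth Go well depth at other peptide contacts (<= 0)
#' @param peptide_sequence one-letter codes (default poly-alanine)
#' @param seed RNG seed for the coordinate jitter
#' @return object of class `toy_spec`
#' @export
toy_spec <- function(groove_length = 12L, floor_width = 12L,
                     peptide_length = 9L, spacing = 0.38,
                     anchor_positions = c(2L, 9L), anchor_depth = -8,
                     background_depth = -0.4,
                     peptide_sequence = strrep("A", peptide_length),
                     seed = 1L) {
  if (peptide_length < 3) stop("toy_spec: peptide_length must be >= 3")
  if (any(anchor_positions < 1 | anchor_positions > peptide_length))
    stop("toy_spec: anchor positions outside the peptide")
  if (anchor_depth > 0 || background_depth > 0)
    stop("toy_spec: well depths must be <= 0")
  if (nchar(peptide_sequence) != peptide_length)
    stop("toy_spec: peptide_sequence length mismatch")
  structure(list(groove_length = as.integer(groove_length),
                 floor_width = as.integer(floor_width),
                 peptide_length = as.integer(peptide_length),
                 spacing = spacing, anchor_positions = as.integer(anchor_positions),
                 anchor_depth = anchor_depth, background_depth = background_depth,
                 peptide_sequence = peptide_sequence, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Build a toy groove-peptide complex
#'
#' Constructs the [toy_spec()] geometry as a [bead_structure()] (receptor
#' chain `"M"`, peptide chain `"P"`), the matching seven-node receptor /
#' peptide region hierarchy (via [build_pmhc_hierarchy()]) and a
#' [probe_set()] anchored at peptide residues 1, middle and last against
#' the nearest floor residues. A small seeded jitter decorrelates repeated
#' builds; a build with any non-bonded bead pair closer than 0.2 nm is
#' rejected and re-jittered (error after 10 tries).
#'
#' @param spec [toy_spec()]
#' @return list with elements `structure`, `hierarchy`, `probes`, `spec`
#' @export
make_toy_complex <- function(spec = toy_spec()) {
  L <- spec$groove_length; W <- spec$floor_width; Lp <- spec$peptide_length
  a <- spec$spacing
  pep_seq <- strsplit(spec$peptide_sequence, "")[[1]]
  set.seed(spec$seed)
  for (try in 1:10) {
    beads <- toy_beads(L, W, Lp, a, pep_seq, jitter_sd = 0.008)
    co <- as.matrix(beads[, c("x", "y", "z")])
    same_res <- outer(paste(beads$chain, beads$resno), paste(beads$chain, beads$resno), "==")
    dd <- as.matrix(stats::dist(co))
    dd[same_res] <- Inf
    if (min(dd) >= 0.2) break
    if (try == 10) stop("make_toy_complex: could not avoid bead overlaps after 10 jitters")
  }
  structure_ <- bead_structure(beads)
  cfg <- list(mhc_chain = "M", peptide_chain = "P",
              helix1_range = c(1L, L), helix1_kink = L %/% 2L + 1L,
              helix2_range = c(L + W + 3L, 2L * L + W + 2L),
              helix2_kink = L + W + 2L + L %/% 2L + 1L)
  hier <- build_pmhc_hierarchy(structure_, cfg)
  pmid <- as.integer(ceiling(Lp / 2))
  # floor residues nearest (in x) to the probed peptide residues
  floor_res <- (L + 2L):(L + 1L + W)
  rt <- residue_table(structure_)
  fx <- vapply(floor_res, function(r) structure_$x[rt$ca_idx[rt$chain == "M" & rt$resno == r]][1], numeric(1))
  px <- vapply(c(1L, pmid, Lp), function(r) structure_$x[rt$ca_idx[rt$chain == "P" & rt$resno == r]][1], numeric(1))
  match_floor <- floor_res[vapply(px, function(x) which.min(abs(fx - x)), integer(1))]
  probes <- probe_set("P", "M", peptide_resno = c(1L, pmid, Lp),
                      receptor_resno = match_floor, ceiling = 3.0)
  list(structure = structure_, hierarchy = hier, probes = probes, spec = spec)
}

# deterministic toy geometry + jitter (RNG state supplied by caller)
toy_beads <- function(L, W, Lp, a, pep_seq, jitter_sd = 0.008) {
  rows <- list()
  add <- function(chain, resno, res, ca, o_off = c(0, 0.17, 0.17), sc_off = NULL) {
    r <- data.frame(chain = chain, resno = resno, res = res,
                    kind = c("CA", "O", if (!is.null(sc_off)) "SC"),
                    x = ca[1] + c(0, o_off[1], sc_off[1]),
                    y = ca[2] + c(0, o_off[2], sc_off[2]),
                    z = ca[3] + c(0, o_off[3], sc_off[3]),
                    stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <<- r
  }
  # CA traces carry an alternating pleat (as in real helices/strands) so
  # that virtual-bond rotations have leverage during chain closure
  zig <- function(i, amp = 0.08) amp * (-1)^i
  # helix rail 1 (side chains face the groove, +y)
  for (i in 1:L)
    add("M", i, "A", c((i - 1) * a, -0.45, 0.5 + zig(i)), sc_off = c(0, 0.21, 0.21))
  # linker to the floor (glycine, no SC; carbonyl points away from the rails)
  add("M", L + 1L, "G", c((L - 1) * a + 0.2, -0.265, 0.29), o_off = c(-0.05, 0, -0.23))
  # floor strip, running back in -x (side chains face up, carbonyls down)
  for (j in 1:W)
    add("M", L + 1L + j, "A", c((W - j) * a, zig(j), 0), o_off = c(0, 0.17, -0.17),
        sc_off = c(0, 0, 0.30))
  # linker to rail 2
  add("M", L + W + 2L, "G", c(-0.2, 0.265, 0.21), o_off = c(0.05, 0, -0.23))
  # helix rail 2 (side chains face the groove, -y)
  for (i in 1:L)
    add("M", L + W + 2L + i, "A", c((i - 1) * a, 0.45, 0.5 + zig(i)), sc_off = c(0, -0.21, 0.21))
  # peptide: bent pose above the floor, ends ~0.2 nm lower than the middle
  x0 <- ((W - 1) * a) / 2 - ((Lp - 1) * a) / 2
  for (i in 1:Lp) {
    z <- 1.0 + 0.2 * sin(pi * (i - 1) / (Lp - 1)) + zig(i, 0.06)
    aa <- pep_seq[i]
    sc <- if (aa == "G") NULL else c(0, 0, -0.30)
    add("P", i, aa, c(x0 + (i - 1) * a, 0, z), o_off = c(0, 0.17, 0.17), sc_off = sc)
  }
  # groove end walls (fixed chain "X"): class I grooves are closed at both
  # ends (A and F pockets); without them the peptide can slide out axially
  for (wall in 1:2) {
    xw <- if (wall == 1L) -0.5 else (W - 1) * a + 0.5
    wch <- c("X", "Y")[wall]
    wres <- 0L
    k <- 0L
    for (yw in c(-0.35, 0, 0.35)) {
      zs <- if (k %% 2L == 0L) c(0.25, 0.6, 0.95) else c(0.95, 0.6, 0.25)
      for (zw in zs) {
        wres <- wres + 1L
        add(wch, wres, "G", c(xw, yw, zw),
            o_off = c(if (wall == 1L) -0.12 else 0.12, 0, 0))
      }
      k <- k + 1L
    }
  }
  df <- do.call(rbind, rows)
  jit <- matrix(stats::runif(3 * nrow(df), -jitter_sd, jitter_sd), ncol = 3)
  # jitter whole residues rigidly so bead offsets within a residue persist
  key <- paste(df$chain, df$resno)
  jres <- jit[match(key, unique(key)), , drop = FALSE]
  df$x <- df$x + jres[, 1]; df$y <- df$y + jres[, 2]; df$z <- df$z + jres[, 3]
  df
}

#' Go-style native-contact potential for a toy complex
#'
#' Builds a [pair_potential()] with per-bead types (typing `"column"`; the
#' structure's `type` column is rewritten to unique labels) rewarding only
#' contacts present in the initial pose: receptor-receptor native contacts
#' get a strong well (keeps the fold), peptide-receptor native SC-SC
#' contacts get the anchor well depth at anchor positions and the
#' background depth elsewhere, and every pair gets a repulsive core below
#' 0.25 nm. Because ground truth is dialled in by construction, these
#' potentials make binder/non-binder outcomes exactly controllable in
#' tests.
#'
#' @param complex from [make_toy_complex()]
#' @param anchor_depth,background_depth well depths (k_B*T_ref, <= 0);
#'   default from the complex's [toy_spec()]
#' @param contact_cutoff native-contact distance cutoff, nm
#' @param well_margin well width beyond the native distance, nm
#' @param fold_depth receptor-receptor native well depth
#' @param repulsion core repulsion height below 0.25 nm
#' @param respect_sequence if `TRUE`, an anchor position only gets the
#'   anchor depth when the peptide residue there is one of the preferred
#'   anchor residues (L/M/I at position 2; V/L/I at the C-terminus)
#' @param stiffness_depth depth of narrow-band intra-peptide CA-CA
#'   `(i, i+3)` wells (<= 0); penalises sharp local bending of the peptide
#'   backbone (a bulge must leave these wells) while leaving rigid-body
#'   tilts and end peeling free
#' @param stiffness_band half-width of the stiffness wells around the
#'   native distance, nm
#' @param bin_width,cutoff potential table discretisation, nm
#' @return list with `potential` and `structure` (the complex structure
#'   with the per-bead `type` column the potential expects)
#' @export
make_go_potential <- function(complex, anchor_depth = complex$spec$anchor_depth,
                              background_depth = complex$spec$background_depth,
                              contact_cutoff = 0.9, well_margin = 0.25,
                              fold_depth = -8, repulsion = 4,
                              respect_sequence = FALSE,
                              stiffness_depth = 0, stiffness_band = 0.12,
                              bin_width = 0.05, cutoff = 1.5) {
  st <- complex$structure
  st$type <- paste0("b", seq_len(nrow(st)))
  n <- nrow(st)
  nb <- round(cutoff / bin_width)
  mids <- (seq_len(nb) - 0.5) * bin_width
  E <- array(0, c(n, n, nb))
  core <- mids < 0.25
  E[, , core] <- repulsion
  co <- bead_coords(st)
  meta <- bead_meta(st)
  dd <- as.matrix(stats::dist(co))
  put_well <- function(i, j, depth, r_nat) {
    sel <- mids >= 0.25 & mids < r_nat + well_margin
    E[i, j, sel] <<- depth
    E[j, i, sel] <<- depth
  }
  is_m <- st$chain == "M"; is_p <- st$chain == "P"
  # receptor fold contacts
  mi <- which(is_m)
  for (i in mi) for (j in mi) {
    if (j <= i) next
    if (abs(meta$ord[i] - meta$ord[j]) < 3) next
    if (dd[i, j] < contact_cutoff) put_well(i, j, fold_depth, dd[i, j])
  }
  # peptide-receptor SC-SC contacts
  anchors <- complex$spec$anchor_positions
  pref <- ANCHOR_PREFERENCE
  pi_ <- which(is_p & st$kind == "SC")
  mi_sc <- which(is_m & st$kind == "SC")
  for (i in pi_) {
    pos <- st$resno[i]
    depth <- background_depth
    if (pos %in% anchors) {
      use_anchor <- TRUE
      if (respect_sequence) {
        want <- if (pos == complex$spec$peptide_length) pref[["9"]] else pref[[as.character(pos)]]
        if (is.null(want)) want <- character(0)
        use_anchor <- st$res[i] %in% want
      }
      if (use_anchor) depth <- anchor_depth
    }
    for (j in mi_sc) if (dd[i, j] < contact_cutoff) put_well(i, j, depth, dd[i, j])
  }
  # groove end walls repel the peptide out to 0.45 nm so it cannot thread
  # between wall beads and slide out axially
  wi <- which(st$chain %in% c("X", "Y"))
  if (length(wi)) {
    wall_range <- mids < 0.45
    for (i in wi) for (j in which(is_p)) {
      E[i, j, wall_range] <- repulsion
      E[j, i, wall_range] <- repulsion
    }
  }
  # peptide backbone stiffness: banded CA-CA (i, i+3) wells
  if (stiffness_depth < 0) {
    pca <- which(is_p & st$kind == "CA")
    for (i in pca) for (j in pca) {
      if (meta$ord[j] - meta$ord[i] != 3L) next
      sel <- mids >= dd[i, j] - stiffness_band & mids < dd[i, j] + stiffness_band
      E[i, j, sel] <- E[i, j, sel] + stiffness_depth
      E[j, i, sel] <- E[j, i, sel] + stiffness_depth
    }
  }
  pot <- pair_potential(st$type, E, bin_width, cutoff, typing = "column")
  list(potential = pot, structure = st)
}

#' Specification of synthetic replica trajectories
#'
#' Statistical stand-in for detachment trajectories: binders fluctuate
#' about the bound baseline; non-binders rise logistically from the
#' baseline toward the 3 nm full-detachment ceiling with a per-replica
#' jittered midpoint. Defaults mirror the study conditions (100 replicas
#' per peptide; a snapshot grid of 200 frames standing for a strided
#' 100000-step run).
#'
#' @param class `"binder"` or `"non-binder"`
#' @param n_replicas replicas to generate
#' @param n_steps snapshots per replica
#' @param midpoint detachment midpoint, snapshots (non-binders)
#' @param slope logistic slope per snapshot
#' @param noise_sd Gaussian noise SD, nm
#' @param baseline length-3 baseline distances (N, mid, C), nm
#' @param ceiling clamp ceiling, nm
#' @param seed RNG seed
#' @return object of class `synthetic_replica_spec`
#' @export
synthetic_replica_spec <- function(class = c("non-binder", "binder"),
                                   n_replicas = 100L, n_steps = 200L,
                                   midpoint = 80, slope = 0.08,
                                   noise_sd = 0.15,
                                   baseline = c(1.08, 1.31, 1.09),
                                   ceiling = 3.0, seed = 1L) {
  class <- match.arg(class)
  if (noise_sd < 0) stop("synthetic_replica_spec: noise_sd must be >= 0")
  if (midpoint < 0 || midpoint > n_steps)
    stop("synthetic_replica_spec: midpoint outside [0, n_steps]")
  structure(list(class = class, n_replicas = as.integer(n_replicas),
                 n_steps = as.integer(n_steps), midpoint = midpoint,
                 slope = slope, noise_sd = noise_sd, baseline = baseline,
                 ceiling = ceiling, seed = as.integer(seed)),
            class = "synthetic_replica_spec")
}

#' Generate a synthetic replica set
#'
#' @param spec [synthetic_replica_spec()]
#' @param peptide_id identifier for the replica set
#' @return a [replica_set()]
#' @export
make_synthetic_replicas <- function(spec = synthetic_replica_spec(),
                                    peptide_id = spec$class) {
  set.seed(spec$seed)
  R <- spec$n_replicas; S <- spec$n_steps
  d <- array(NA_real_, c(R, S, 3), dimnames = list(NULL, NULL, c("N", "mid", "C")))
  t <- seq_len(S)
  for (r in seq_len(R)) {
    mid_r <- if (spec$class == "non-binder")
      spec$midpoint * stats::runif(1, 0.8, 1.2) else Inf
    for (p in 1:3) {
      base <- spec$baseline[p]
      rise <- if (is.finite(mid_r))
        (spec$ceiling + 0.5 - base) / (1 + exp(-spec$slope * (t - mid_r)))
      else 0
      d[r, , p] <- base + rise + stats::rnorm(S, 0, spec$noise_sd)
    }
  }
  d <- pmin(pmax(d, 0.01), spec$ceiling)
  replica_set(peptide_id = peptide_id, sequence = NA_character_,
              steps = t, distances = d, ceiling = spec$ceiling)
}
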