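#' Periodic simulated-annealing temperature schedule
#'
#' Temperature modulation for the Monte Carlo run:
#' \deqn{T(k) = s_T + \frac{A}{2}\left(1 + \cos\frac{2\pi k}{\Omega}\right)}
#' periodic in the step counter `k` with period `omega`, oscillating between
#' a maximum of `shift + amplitude` (at the start of each period) and a
#' minimum of `shift`. Repeated annealing cycles let the system escape
#' minima at the hot phase and settle into low-energy states at the cold
#' phase. Defaults: amplitude 600 K, period 5000 steps, shift 0 K,
#' 100000 steps in total.
#'
#' @param amplitude modulation amplitude A, Kelvin
#' @param omega steps per period
#' @param shift minimum temperature s_T, Kelvin
#' @param total_steps number of MC steps of a run
#' @return object of class `anneal_schedule`
#' @export
anneal_schedule <- function(amplitude = 600, omega = 5000, shift = 0,
                            total_steps = 100000) {
  if (amplitude < 0) stop("anneal_schedule: amplitude must be >= 0")
  if (omega < 2) stop("anneal_schedule: omega must be >= 2")
  if (shift < 0) stop("anneal_schedule: shift must be >= 0")
  structure(list(amplitude = amplitude, omega = omega, shift = shift,
                 total_steps = as.integer(total_steps)),
            class = "anneal_schedule")
}

#' Temperature at a Monte Carlo step
#' @param k step counter(s), 0-based
#' @param schedule [anneal_schedule()]
#' @return temperature(s), Kelvin
#' @export
temperature_at <- function(k, schedule = anneal_schedule()) {
  if (any(k < 0)) stop("temperature_at: negative step")
  schedule$shift + (schedule$amplitude / 2) * (1 + cos(2 * pi * k / schedule$omega))
}

#' Metropolis acceptance test
#'
#' Accepts downhill moves always; uphill moves with probability
#' `exp(-delta_e * t_ref / T)` (energies in k_B*T_ref units). At `T = 0`
#' every uphill move is rejected.
#'
#' @param delta_e energy difference, k_B*T_ref units
#' @param temperature Kelvin, >= 0
#' @param t_ref reference temperature of the energy units, Kelvin
#' @return logical, move accepted
#' @export
metropolis_accept <- function(delta_e, temperature, t_ref = 300) {
  if (temperature < 0) stop("metropolis_accept: negative temperature")
  if (delta_e <= 0) return(TRUE)
  if (temperature == 0) return(FALSE)
  stats::runif(1) < exp(-delta_e * t_ref / temperature)
}

# --- closure / move geometry precomputation -------------------------------

# split sorted integers into maximal consecutive runs
consecutive_runs <- function(v) {
  v <- sort(unique(v))
  split(v, cumsum(c(1L, diff(v) != 1L)))
}

# per-node runtime description (bead indices, closure breaks, zones)
node_runtime <- function(structure, hierarchy, zone = 3L,
                         which = seq_along(hierarchy$nodes)) {
  rt <- residue_table(structure)
  out <- lapply(which, function(ni) {
    nd <- hierarchy$nodes[[ni]]
    crt <- rt[rt$chain == nd$chain, , drop = FALSE]
    Lc <- nrow(crt)
    moved_res <- intersect(ranges_to_set(nd$ranges), crt$resno)
    moved_ord <- sort(crt$ord[match(moved_res, crt$resno)])
    in_moved <- logical(Lc)
    in_moved[moved_ord] <- TRUE
    res_beads <- function(ords) {
      unlist(lapply(ords, function(o) {
        r <- crt[crt$ord == o, ]
        c(r$ca_idx, r$o_idx, if (!is.na(r$sc_idx)) r$sc_idx)
      }), use.names = FALSE)
    }
    ca_of <- function(o) crt$ca_idx[crt$ord == o]
    idx <- res_beads(moved_ord)
    breaks <- list()
    for (run in consecutive_runs(moved_ord)) {
      s <- run[1]; e <- run[length(run)]
      if (s > 1L && !in_moved[s - 1L]) { # N-side break
        u <- s - 1L
        z1 <- u
        while (z1 > 1L && !in_moved[z1 - 1L] && (u - z1 + 1L) < zone) z1 <- z1 - 1L
        axes <- list()
        jlo <- max(1L, z1 - 1L)
        for (j in if (u - 2L >= jlo) jlo:(u - 2L) else integer(0)) {
          if (in_moved[j] || in_moved[j + 1L]) next
          axes[[length(axes) + 1L]] <- list(p = ca_of(j), q = ca_of(j + 1L),
                                            rot = res_beads((j + 1L):u))
        }
        # a very short flank running to the chain start has no usable CCD
        # axis: close it as a rigid hinge about its free end instead
        rigid <- (z1 == 1L && u <= 2L)
        breaks[[length(breaks) + 1L]] <- list(
          u = ca_of(u), v = ca_of(s), zone = res_beads(z1:u), axes = axes,
          rigid = rigid, far_ca = if (rigid) ca_of(1L) else NA_integer_)
      }
      if (e < Lc && !in_moved[e + 1L]) { # C-side break
        u <- e + 1L
        z2 <- u
        while (z2 < Lc && !in_moved[z2 + 1L] && (z2 - u + 1L) < zone) z2 <- z2 + 1L
        axes <- list()
        mhi <- min(z2 + 1L, Lc - 1L)
        for (m in if (mhi >= u + 1L) (u + 1L):mhi else integer(0)) {
          if (in_moved[m] || in_moved[m + 1L]) next
          axes[[length(axes) + 1L]] <- list(p = ca_of(m), q = ca_of(m + 1L),
                                            rot = res_beads(u:min(m, z2)))
        }
        # order axes far-to-near for better-conditioned sweeps
        axes <- rev(axes)
        rigid <- (z2 == Lc && Lc - u <= 1L)
        breaks[[length(breaks) + 1L]] <- list(
          u = ca_of(u), v = ca_of(e), zone = res_beads(u:z2), axes = axes,
          rigid = rigid, far_ca = if (rigid) ca_of(Lc) else NA_integer_)
      }
    }
    zone_beads <- unlist(lapply(breaks, `[[`, "zone"), use.names = FALSE)
    list(idx = as.integer(idx),
         ca_idx = as.integer(crt$ca_idx[match(moved_ord, crt$ord)]),
         affected = as.integer(sort(unique(c(idx, zone_beads)))),
         tmax = nd$max_trans, rmax = nd$max_rot, weight = nd$weight,
         breaks = breaks, label = nd$label)
  })
  names(out) <- NULL
  out
}

#' Propose a rigid-body natural move for a hierarchy node
#'
#' Draws a symmetric random rigid-body proposal: translation uniform in the
#' cube `[-t_max, t_max]^3`, rotation axis uniform on the sphere, rotation
#' angle uniform in `[-theta_max, theta_max]` degrees, pivot at the centroid
#' of the node's CA beads. Deterministic given the R RNG state.
#'
#' @param structure bead_structure
#' @param hierarchy region_hierarchy
#' @param node node index in the hierarchy
#' @return a `move_proposal`: list with `node`, `idx` (bead rows moved),
#'   `translation` (nm), `axis`, `angle` (degrees), `pivot` (nm)
#' @export
propose_region_move <- function(structure, hierarchy, node) {
  nrt <- node_runtime(structure, hierarchy, which = node)[[1]]
  pr <- cpp_propose(nrt$tmax, nrt$rmax)
  co <- bead_coords(structure)
  pivot <- colMeans(co[nrt$ca_idx, , drop = FALSE])
  structure(list(node = node, idx = nrt$idx, translation = pr[1:3],
                 axis = pr[4:6], angle = pr[7], pivot = pivot),
            class = "move_proposal")
}

#' Apply a rigid-body move proposal
#'
#' Rotates the proposal's beads about its axis through the pivot, then
#' translates them; all other beads are untouched and the internal geometry
#' of the moved region is preserved exactly.
#'
#' @param structure bead_structure
#' @param proposal from [propose_region_move()]
#' @return bead_structure after the move (chain breaks not yet closed)
#' @export
apply_move <- function(structure, proposal) {
  co <- cpp_apply_move(bead_coords(structure), as.integer(proposal$idx),
                       proposal$pivot, proposal$axis, proposal$angle,
                       proposal$translation)
  set_bead_coords(structure, co)
}

#' Close chain breaks left by a rigid region move
#'
#' Repairs the backbone at the boundaries of a moved region with a cyclic
#' coordinate-descent style algorithm: residues in a closure zone (default
#' 3 residues flanking each break, on the stationary side) are rotated
#' about CA-CA virtual bonds, each rotation choosing the angle that brings
#' the broken CA-CA virtual bond closest to its pre-move length. O and SC
#' beads ride rigidly with their residues. Non-convergence is flagged; the
#' sampler auto-rejects such proposals.
#'
#' @param structure bead_structure after the move (breaks open)
#' @param hierarchy region_hierarchy
#' @param node moved node index
#' @param ref bead_structure before the move (supplies the target CA-CA
#'   bond lengths across each break)
#' @param zone closure-zone length, residues per break side
#' @param tolerance residual tolerance, nm
#' @param max_sweeps maximum CCD sweeps
#' @param max_angle per-axis rotation cap, radians
#' @return list with `structure`, `residuals` (nm, per break) and
#'   `converged`
#' @export
close_chain <- function(structure, hierarchy, node, ref, zone = 3L,
                        tolerance = 0.02, max_sweeps = 30L, max_angle = 1.0) {
  nrt <- node_runtime(structure, hierarchy, zone, which = node)[[1]]
  if (!length(nrt$breaks))
    return(list(structure = structure, residuals = numeric(0), converged = TRUE))
  refco <- bead_coords(ref)
  d0 <- vapply(nrt$breaks, function(b)
    sqrt(sum((refco[b$u, ] - refco[b$v, ])^2)), numeric(1))
  res <- cpp_close_breaks(bead_coords(structure), nrt$breaks, d0, tolerance,
                          as.integer(max_sweeps), max_angle)
  list(structure = set_bead_coords(structure, res$coords),
       residuals = res$residuals, converged = res$converged)
}

# --- the sampler ----------------------------------------------------------

#' Run one hierarchical natural-move Monte Carlo simulation
#'
#' At every step a hierarchy node is chosen by selection weight, a rigid
#' translation/rotation is proposed and applied, the resulting chain breaks
#' are closed, and the move is accepted or rejected by the Metropolis rule
#' at the annealing temperature [temperature_at()]. Incremental energies
#' are periodically checked against a full recompute; a mismatch aborts
#' with an error. Runs are bit-reproducible for a fixed seed.
#'
#' @param structure initial bead_structure
#' @param hierarchy region_hierarchy
#' @param pot [pair_potential()]
#' @param schedule [anneal_schedule()] (`total_steps` sets the run length)
#' @param seed RNG seed for this run
#' @param params [scaling_params()]
#' @param probes optional [probe_set()]; probe CA-CA distances are then
#'   recorded every `probe_stride` steps
#' @param snapshot_stride steps between stored coordinate snapshots
#' @param probe_stride steps between probe-distance records
#' @param store_snapshots keep full coordinate snapshots (memory-heavy for
#'   long runs; probe tracking works without them)
#' @param zone closure-zone length (residues)
#' @param closure_tol closure residual tolerance, nm
#' @param closure_max_sweeps maximum CCD sweeps per move
#' @param resync_every steps between incremental/full energy consistency
#'   checks
#' @param t_ref reference temperature of the energy units, Kelvin
#' @return object of class `mc_trajectory`: step/energy/temperature traces,
#'   acceptance bookkeeping, optional snapshots (`array [n_snap, n_beads,
#'   3]`), probe-distance track, final structure
#' @export
run_mcmc <- function(structure, hierarchy, pot, schedule = anneal_schedule(),
                     seed = 1L, params = scaling_params(), probes = NULL,
                     snapshot_stride = 100L, probe_stride = snapshot_stride,
                     store_snapshots = TRUE, zone = 3L, closure_tol = 0.02,
                     closure_max_sweeps = 30L, resync_every = 2000L,
                     t_ref = 300) {
  set.seed(as.integer(seed))
  sys <- prep_system(structure, pot,
                     peptide_chain = if (!is.null(probes)) probes$peptide_chain)
  nodes <- node_runtime(structure, hierarchy, zone)
  tp <- matrix(integer(0), 0, 2)
  if (!is.null(probes)) tp <- probe_ca_indices(structure, probes)
  res <- cpp_run_mcmc(sys$coords, sys$type, sys$chain, sys$ord, sys$group,
                      as.numeric(pot$energies), length(pot$types),
                      dim(pot$energies)[3], pot$bin_width, pot$cutoff,
                      pot$min_seq_sep, params$s0, params$r0, nodes,
                      schedule$amplitude, schedule$omega, schedule$shift,
                      t_ref, schedule$total_steps, as.integer(snapshot_stride),
                      tp, as.integer(probe_stride), as.integer(resync_every),
                      closure_tol, as.integer(closure_max_sweeps), 1.0,
                      store_snapshots)
  out <- list(
    steps = seq_len(schedule$total_steps),
    energy = res$energy, temperature = res$temperature,
    accepted = res$accepted, node = res$node,
    node_labels = vapply(nodes, `[[`, character(1), "label"),
    acc_count = res$acc_count, prop_count = res$prop_count,
    closure_fail = res$closure_fail,
    final_structure = set_bead_coords(structure, res$final_coords),
    final_energy = res$final_energy,
    template = structure, seed = seed, schedule = schedule)
  if (store_snapshots) {
    out$snapshots <- res$snapshots
    out$snap_steps <- res$snap_steps
  }
  if (!is.null(probes)) {
    out$probe_track <- res$track
    out$probe_steps <- res$track_steps
    out$probes <- probes
  }
  class(out) <- "mc_trajectory"
  out
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat("mc_trajectory:", length(x$steps), "steps, seed", x$seed,
      sprintf("| final energy %.4g | acceptance %.1f%% | closure rejects %d\n",
              x$final_energy, 100 * mean(x$accepted), x$closure_fail))
  invisible(x)
}

#' Run independent Monte Carlo replicas
#'
#' Repeats [run_mcmc()] with seeds `base_seed + 1 ... base_seed +
#' n_replicas` and collects the clamped probe-distance trajectories into a
#' [replica_set()]. Replicas are independent; results are identical
#' regardless of execution order.
#'
#' @inheritParams run_mcmc
#' @param n_replicas number of replicas
#' @param base_seed replica `i` uses seed `base_seed + i`
#' @param peptide_id identifier stored in the replica set
#' @param keep_trajectories also return the full `mc_trajectory` objects
#'   (attribute `"trajectories"`)
#' @param ... further arguments passed to [run_mcmc()]
#' @return a [replica_set()]
#' @export
run_replicas <- function(structure, hierarchy, pot, probes,
                         schedule = anneal_schedule(), n_replicas = 1L,
                         base_seed = 0L, params = scaling_params(),
                         peptide_id = "peptide", probe_stride = 100L,
                         keep_trajectories = FALSE, ...) {
  stopifnot(n_replicas >= 1)
  trajs <- vector("list", n_replicas)
  dists <- NULL
  seeds <- base_seed + seq_len(n_replicas)
  for (i in seq_len(n_replicas)) {
    tr <- run_mcmc(structure, hierarchy, pot, schedule, seed = seeds[i],
                   params = params, probes = probes,
                   probe_stride = probe_stride,
                   store_snapshots = keep_trajectories, ...)
    if (is.null(dists))
      dists <- array(NA_real_, c(n_replicas, nrow(tr$probe_track), 3),
                     dimnames = list(NULL, NULL, probes$labels))
    dists[i, , ] <- pmin(tr$probe_track, probes$ceiling)
    steps <- tr$probe_steps
    if (keep_trajectories) trajs[[i]] <- tr
  }
  seq_pep <- tryCatch(chain_sequence(structure, probes$peptide_chain),
                      error = function(e) NA_character_)
  rs <- replica_set(peptide_id = peptide_id, sequence = seq_pep,
                    steps = steps, distances = dists, seeds = seeds,
                    ceiling = probes$ceiling)
  if (keep_trajectories) attr(rs, "trajectories") <- trajs
  rs
}
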