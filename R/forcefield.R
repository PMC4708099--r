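#' Short-range pair-interaction scaling
#'
#' Scaling parameters for the coarse-grained pair potential. All pair
#' interaction energies are multiplied by the continuous function
#' \deqn{s(r) = s_0 + (1 - s_0) (r/r_0)^6 \quad (r < r_0), \qquad s(r) = 1
#' \quad (r \ge r_0)}
#' which damps interactions at short range so that a small peptide can
#' escape deep energy minima, while leaving everything beyond \eqn{r_0}
#' untouched. Defaults: \eqn{s_0 = 0.15} (dimensionless floor) and
#' \eqn{r_0 = 0.7} nm, roughly the size of a large amino acid.
#'
#' @param s0 dimensionless scaling floor, in (0, 1]
#' @param r0 crossover distance, nm
#' @return object of class `scaling_params`
#' @export
scaling_params <- function(s0 = 0.15, r0 = 0.7) {
  if (!(s0 > 0 && s0 <= 1)) stop("scaling_params: s0 must be in (0, 1]")
  if (r0 <= 0) stop("scaling_params: r0 must be positive")
  structure(list(s0 = s0, r0 = r0), class = "scaling_params")
}

#' Evaluate the short-range scaling function s(r)
#'
#' @param r distance(s), nm, non-negative
#' @param params [scaling_params()]
#' @return dimensionless factor(s) in `[s0, 1]`
#' @export
scale_factor <- function(r, params = scaling_params()) {
  if (any(r < 0)) stop("scale_factor: negative distance")
  ifelse(r < params$r0, params$s0 + (1 - params$s0) * (r / params$r0)^6, 1.0)
}

#' Distance-binned knowledge-based pair potential
#'
#' Tabulated pair energies per bead-type pair and distance bin. Energies
#' are dimensionless multiples of \eqn{k_B T_{ref}} with \eqn{T_{ref} =
#' 300} K (knowledge-based potentials carry no absolute scale). Bins are
#' half-open, `[k*w, (k+1)*w)`; a distance at or beyond the cutoff scores
#' zero. Pairs of beads closer than `min_seq_sep` residues along the same
#' chain (including intra-residue pairs) are excluded from the non-bonded
#' sum.
#'
#' @param types character vector of bead type labels
#' @param energies numeric array `[n_types, n_types, n_bins]`, symmetric in
#'   the first two dimensions
#' @param bin_width bin width, nm (default 0.05)
#' @param cutoff interaction cutoff, nm; must equal `bin_width * n_bins`
#' @param min_seq_sep minimum residue separation within one chain for a
#'   pair to interact (default 3, i.e. `|i-j| <= 2` excluded)
#' @param typing how beads are mapped to types: `"default"` uses
#'   [default_bead_types()], `"column"` uses the structure's `type` column
#'   as-is (used by per-bead Go-style potentials)
#' @return object of class `pair_potential`
#' @export
pair_potential <- function(types, energies, bin_width = 0.05,
                           cutoff = bin_width * dim(energies)[3],
                           min_seq_sep = 3L, typing = c("default", "column")) {
  typing <- match.arg(typing)
  nt <- length(types)
  if (!is.array(energies) || length(dim(energies)) != 3 ||
      dim(energies)[1] != nt || dim(energies)[2] != nt)
    stop("pair_potential: energies must be an [n_types, n_types, n_bins] array")
  if (!all(is.finite(energies))) stop("pair_potential: non-finite energies")
  nb <- dim(energies)[3]
  if (abs(cutoff - bin_width * nb) > 1e-9)
    stop("pair_potential: cutoff (", cutoff, ") must equal bin_width * n_bins (",
         bin_width * nb, ")")
  if (max(abs(energies - aperm(energies, c(2, 1, 3)))) > 1e-12)
    stop("pair_potential: energy table not symmetric in the type pair")
  structure(list(types = types, energies = energies, bin_width = bin_width,
                 cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep),
                 typing = typing),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat("pair_potential:", length(x$types), "bead types,", dim(x$energies)[3],
      "bins of", x$bin_width, "nm (cutoff", x$cutoff, "nm), typing:", x$typing, "\n")
  invisible(x)
}

# bead type labels of a structure under the potential's typing scheme
potential_types <- function(structure, pot) {
  if (pot$typing == "column") structure$type else default_bead_types(structure)
}

# 1-based type indices; errors on any bead type missing from the table
type_index <- function(structure, pot) {
  idx <- match(potential_types(structure, pot), pot$types)
  if (anyNA(idx)) {
    bad <- unique(potential_types(structure, pot)[is.na(idx)])
    stop("unknown bead type(s) for this potential: ", paste(bad, collapse = ", "))
  }
  idx
}

#' Scaled pair energy between two bead types at a distance
#'
#' Returns the tabulated energy for the bin containing `r`, multiplied by
#' the short-range scaling [scale_factor()]. Distances at or beyond the
#' cutoff, and pairs excluded by the sequence-separation rule, score zero.
#'
#' @param r distance(s), nm
#' @param type_i,type_j bead type labels
#' @param pot [pair_potential()]
#' @param params [scaling_params()]
#' @param seq_sep residue separation if the beads share a chain (default
#'   `Inf`: different chains, never excluded)
#' @return energy in k_B*T_ref units
#' @export
pair_energy <- function(r, type_i, type_j, pot, params = scaling_params(),
                        seq_sep = Inf) {
  if (any(r < 0)) stop("pair_energy: negative distance")
  ti <- match(type_i, pot$types); tj <- match(type_j, pot$types)
  if (is.na(ti) || is.na(tj))
    stop("pair_energy: unknown bead type pair (", type_i, ", ", type_j, ")")
  if (seq_sep < pot$min_seq_sep) return(rep(0, length(r)))
  nb <- dim(pot$energies)[3]
  bin <- floor(r / pot$bin_width) + 1L
  e <- ifelse(r >= pot$cutoff | bin > nb, 0,
              pot$energies[cbind(ti, tj, pmin(bin, nb))])
  e * scale_factor(r, params)
}

# integer system description shared by the energy / sampling kernels
prep_system <- function(structure, pot, peptide_chain = NULL) {
  meta <- bead_meta(structure)
  list(coords = bead_coords(structure),
       type = type_index(structure, pot),
       chain = meta$chain,
       ord = meta$ord,
       group = as.integer(structure$chain %in% (peptide_chain %||% character(0))))
}

#' Total non-bonded energy of a bead structure
#'
#' Sums the scaled pair energy over all non-excluded bead pairs. Returns a
#' breakdown into peptide-receptor, intra-receptor and intra-peptide
#' subtotals (all chains not named in `peptide_chain` count as receptor).
#'
#' @param structure bead_structure
#' @param pot [pair_potential()]
#' @param params [scaling_params()]
#' @param peptide_chain chain identifier(s) of the peptide (optional; only
#'   affects the subtotals)
#' @return object of class `energy_breakdown`: list with `total`,
#'   `peptide_receptor`, `intra_receptor`, `intra_peptide`
#' @export
total_energy <- function(structure, pot, params = scaling_params(),
                         peptide_chain = NULL) {
  sys <- prep_system(structure, pot, peptide_chain)
  e <- cpp_total_energy(sys$coords, sys$type, sys$chain, sys$ord, sys$group,
                        as.numeric(pot$energies), length(pot$types),
                        dim(pot$energies)[3], pot$bin_width, pot$cutoff,
                        pot$min_seq_sep, params$s0, params$r0)
  structure(list(total = e[1], peptide_receptor = e[2],
                 intra_receptor = e[3], intra_peptide = e[4]),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy (k_B*T_ref): total %.6g [pep-rec %.6g, intra-rec %.6g, intra-pep %.6g]\n",
              x$total, x$peptide_receptor, x$intra_receptor, x$intra_peptide))
  invisible(x)
}

#' Incremental energy change of a region move
#'
#' Energy difference caused by moving the beads listed in `moved_idx` from
#' `old_coords` to their positions in `structure`, equal (to numerical
#' precision) to `total_energy(after) - total_energy(before)` but computed
#' only over pairs with at least one moved endpoint.
#'
#' @param structure bead_structure *after* the move
#' @param moved_idx integer bead row indices whose positions changed
#' @param old_coords matrix `length(moved_idx) x 3` of the previous
#'   positions (nm)
#' @param pot [pair_potential()]
#' @param params [scaling_params()]
#' @return scalar energy difference, k_B*T_ref units
#' @export
delta_energy <- function(structure, moved_idx, old_coords, pot,
                         params = scaling_params()) {
  old_coords <- rbind(old_coords)
  if (nrow(old_coords) != length(moved_idx))
    stop("delta_energy: moved_idx has length ", length(moved_idx),
         " but old_coords has ", nrow(old_coords), " rows")
  sys <- prep_system(structure, pot)
  args <- list(as.integer(moved_idx), sys$type, sys$chain, sys$ord,
               as.numeric(pot$energies), length(pot$types),
               dim(pot$energies)[3], pot$bin_width, pot$cutoff,
               pot$min_seq_sep, params$s0, params$r0)
  e_after <- do.call(cpp_subset_energy, c(list(sys$coords), args))
  before <- sys$coords
  before[moved_idx, ] <- old_coords
  e_before <- do.call(cpp_subset_energy, c(list(before), args))
  e_after - e_before
}

#' A neutral default pair potential
#'
#' Generic excluded-volume table for exploratory runs when no
#' knowledge-based table is supplied: a soft repulsive core (+4 k_B*T_ref
#' below 0.25 nm) for every pair and a shallow attraction (-0.3) between
#' side-chain beads from 0.25 nm to 0.8 nm. Science-grade runs should load
#' a real knowledge-based table with [read_pair_potential()].
#'
#' @param bin_width bin width, nm
#' @param cutoff cutoff, nm
#' @return [pair_potential()]
#' @export
default_pair_potential <- function(bin_width = 0.05, cutoff = 1.5) {
  types <- c("CA", "O", paste0("SC_", setdiff(AA1, "G")))
  nb <- round(cutoff / bin_width)
  nt <- length(types)
  E <- array(0, c(nt, nt, nb))
  mids <- (seq_len(nb) - 0.5) * bin_width
  E[, , mids < 0.25] <- 4
  sc <- grepl("^SC_", types)
  att <- mids >= 0.25 & mids < 0.8
  E[sc, sc, att] <- E[sc, sc, att] - 0.3
  pair_potential(types, E, bin_width, cutoff)
}
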