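#' Peptide-groove probe distances
#'
#' Detachment is monitored through three CA-CA probes between peptide
#' residues and residues of the MHC binding floor: the peptide N-terminus,
#' middle and C-terminus (for HLA-A*02:01 and a 9-mer, peptide residues 1,
#' 5, 9 against MHC residues 99, 28, 117). Distances above the clamp
#' ceiling (default 3 nm) count as full detachment and are set to the
#' ceiling.
#'
#' @param peptide_chain,receptor_chain chain identifiers
#' @param peptide_resno integer(3): peptide CA residues (N, mid, C)
#' @param receptor_resno integer(3): matched receptor CA residues
#' @param ceiling clamp ceiling, nm
#' @return object of class `probe_set`
#' @export
probe_set <- function(peptide_chain, receptor_chain,
                      peptide_resno = c(1L, 5L, 9L),
                      receptor_resno = c(99L, 28L, 117L), ceiling = 3.0) {
  stopifnot(length(peptide_resno) == 3, length(receptor_resno) == 3)
  if (ceiling <= 0) stop("probe_set: ceiling must be positive")
  structure(list(peptide_chain = peptide_chain,
                 receptor_chain = receptor_chain,
                 peptide_resno = as.integer(peptide_resno),
                 receptor_resno = as.integer(receptor_resno),
                 labels = c("N", "mid", "C"), ceiling = ceiling),
            class = "probe_set")
}

# CA bead row indices for the three probes; errors on missing residues
probe_ca_indices <- function(structure, probes) {
  rt <- residue_table(structure)
  pick <- function(chain, resno) {
    i <- which(rt$chain == chain & rt$resno == resno)
    if (!length(i)) stop("probe residue not found: chain ", chain, " residue ", resno)
    rt$ca_idx[i]
  }
  cbind(vapply(probes$peptide_resno, pick, integer(1), chain = probes$peptide_chain),
        vapply(probes$receptor_resno, pick, integer(1), chain = probes$receptor_chain))
}

#' Unclamped probe distances of one snapshot
#'
#' @param structure bead_structure (a snapshot)
#' @param probes [probe_set()]
#' @return named numeric(3): Euclidean CA-CA distances (N, mid, C), nm
#' @export
probe_distances <- function(structure, probes) {
  idx <- probe_ca_indices(structure, probes)
  co <- bead_coords(structure)
  d <- sqrt(rowSums((co[idx[, 1], , drop = FALSE] - co[idx[, 2], , drop = FALSE])^2))
  stats::setNames(d, probes$labels)
}

#' Clamp a distance at the full-detachment ceiling
#' @param d distance(s), nm, non-negative
#' @param ceiling clamp ceiling, nm (default 3)
#' @return `min(d, ceiling)`
#' @export
clamp_distance <- function(d, ceiling = 3.0) {
  if (any(d < 0)) stop("clamp_distance: negative distance")
  pmin(d, ceiling)
}

#' Replica set of clamped probe-distance trajectories
#'
#' The unit of all detachment analysis: for one peptide, the clamped probe
#' distances of every replica on a common snapshot grid.
#'
#' @param peptide_id identifier
#' @param sequence peptide sequence (one-letter codes) or `NA`
#' @param steps integer vector: snapshot step indices (shared by replicas)
#' @param distances numeric array `[n_replicas, n_steps, 3]`, nm, clamped
#' @param seeds per-replica seeds (optional)
#' @param ceiling clamp ceiling used, nm
#' @return object of class `replica_set`
#' @export
replica_set <- function(peptide_id, sequence, steps, distances,
                        seeds = NULL, ceiling = 3.0) {
  if (length(dim(distances)) != 3 || dim(distances)[3] != 3)
    stop("replica_set: distances must be an [n_replicas, n_steps, 3] array")
  if (dim(distances)[2] != length(steps))
    stop("replica_set: steps length does not match the snapshot grid")
  if (any(distances > ceiling + 1e-9, na.rm = TRUE))
    stop("replica_set: distances exceed the clamp ceiling")
  if (is.null(dimnames(distances)[[3]])) dimnames(distances)[[3]] <- c("N", "mid", "C")
  structure(list(peptide_id = peptide_id, sequence = sequence,
                 steps = as.integer(steps), distances = distances,
                 n_replicas = dim(distances)[1], seeds = seeds,
                 ceiling = ceiling),
            class = "replica_set")
}

#' @export
print.replica_set <- function(x, ...) {
  cat("replica_set '", x$peptide_id, "': ", x$n_replicas, " replicas x ",
      length(x$steps), " snapshots, ceiling ", x$ceiling, " nm\n", sep = "")
  invisible(x)
}

#' Mean and standard error of probe distances across replicas
#'
#' @param replicas [replica_set()]
#' @return data.frame with columns `step`, `probe`, `mean`, `sem` (`sem` is
#'   `NA` for a single replica)
#' @export
mean_sem_curves <- function(replicas) {
  d <- replicas$distances
  n <- dim(d)[1]
  out <- do.call(rbind, lapply(seq_len(3), function(p) {
    dp <- matrix(d[, , p], nrow = n)
    m <- colMeans(dp)
    s <- if (n > 1) apply(dp, 2, stats::sd) / sqrt(n) else rep(NA_real_, dim(d)[2])
    data.frame(step = replicas$steps, probe = dimnames(d)[[3]][p],
               mean = m, sem = s, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-peptide detachment score
#'
#' The scalar summary compared against experimental binding data: the mean
#' of the clamped probe distances over probes, snapshots and replicas.
#' Larger scores mean faster/fuller detachment, so non-binders are expected
#' to score higher than binders. The probe subset and an optional tail
#' window are configurable.
#'
#' @param replicas [replica_set()]
#' @param probes which probes enter the average (default all three)
#' @param tail_frac use only the last fraction of snapshots (default 1 =
#'   all snapshots)
#' @return scalar score, nm
#' @export
detachment_score <- function(replicas, probes = c("N", "mid", "C"),
                             tail_frac = 1) {
  d <- replicas$distances[, , probes, drop = FALSE]
  ns <- dim(d)[2]
  keep <- seq.int(max(1L, ns - ceiling(tail_frac * ns) + 1L), ns)
  mean(d[, keep, , drop = FALSE])
}

#' Classify the detachment pathway of a single replica
#'
#' Each probe's detachment time is the first snapshot at which its clamped
#' distance exceeds `threshold` and stays above it for `window` consecutive
#' snapshots (infinite if never). Classes: `stable` (no probe detaches),
#' `C-first` / `N-first` (that end leads the other by more than `margin`
#' snapshots and does not trail the middle), `simultaneous-ends` (both ends
#' within `margin` of each other), `middle-first` (the middle leads both
#' ends by more than `margin`). The taxonomy also names an `ends-inward`
#' mode (ends bending inwards while the middle leaves first with the ends
#' pinned); it is retained as a level for completeness but is not
#' distinguishable from `middle-first` by threshold times alone.
#'
#' @param replicas [replica_set()]
#' @param replica replica index
#' @param threshold detachment threshold, nm
#' @param window persistence window, snapshots
#' @param margin tie margin between detachment times, snapshots
#' @return factor level among `stable`, `N-first`, `C-first`,
#'   `simultaneous-ends`, `middle-first`, `ends-inward`
#' @export
classify_pathway <- function(replicas, replica = 1L, threshold = 2.0,
                             window = 10L, margin = 5L) {
  d <- replicas$distances[replica, , , drop = FALSE]
  t_det <- vapply(seq_len(3), function(p)
    first_sustained(d[1, , p] > threshold, window), numeric(1))
  names(t_det) <- dimnames(replicas$distances)[[3]]
  tN <- t_det["N"]; tM <- t_det["mid"]; tC <- t_det["C"]
  lv <- c("stable", "N-first", "C-first", "simultaneous-ends",
          "middle-first", "ends-inward")
  cls <-
    if (all(is.infinite(t_det))) "stable"
    else if (is.finite(tM) && tM < tN - margin && tM < tC - margin) "middle-first"
    else if (is.finite(tN) && is.finite(tC) && abs(tN - tC) <= margin) "simultaneous-ends"
    else if (tC < tN) "C-first"
    else "N-first"
  factor(cls, levels = lv)
}

# first index where `flag` holds for `window` consecutive entries, else Inf
first_sustained <- function(flag, window) {
  n <- length(flag)
  window <- min(window, n)
  r <- rle(flag)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  hit <- which(r$values & r$lengths >= window)
  if (!length(hit)) Inf else starts[hit[1]]
}

#' Pathway-class table for all replicas
#' @inheritParams classify_pathway
#' @return factor vector, one class per replica
#' @export
classify_pathways <- function(replicas, threshold = 2.0, window = 10L,
                              margin = 5L) {
  cls <- lapply(seq_len(replicas$n_replicas), classify_pathway,
                replicas = replicas, threshold = threshold, window = window,
                margin = margin)
  factor(vapply(cls, as.character, character(1)), levels = levels(cls[[1]]))
}

#' Area under the ROC curve for binder/non-binder discrimination
#'
#' Mann-Whitney formulation: the probability that a randomly drawn
#' non-binder scores higher than a randomly drawn binder, ties counted one
#' half. The positive class is the non-binder (larger detachment score =
#' weaker binding).
#'
#' @param scores per-peptide detachment scores
#' @param labels factor/character with levels `binder` / `non-binder`
#' @return AROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- scores[labels == "non-binder"]
  neg <- scores[labels == "binder"]
  if (!length(pos) || !length(neg))
    stop("auroc: need both binder and non-binder labels")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Pearson correlation between detachment scores and binding affinity
#'
#' @param scores per-peptide detachment scores
#' @param affinity experimental affinities (e.g. IC50, nM)
#' @param transform applied to `affinity` before correlating; the default
#'   `log10` is the conventional choice for IC50 values
#' @return product-moment correlation in `[-1, 1]`
#' @export
pearson_r <- function(scores, affinity, transform = log10) {
  if (length(scores) < 3) stop("pearson_r: need at least 3 points")
  y <- transform(affinity)
  if (stats::sd(scores) == 0 || stats::sd(y) == 0)
    stop("pearson_r: constant input vector")
  stats::cor(scores, y, method = "pearson")
}

#' Bootstrap standard deviation of the AROC versus replica count
#'
#' For each requested replica count `n`: repeat `B` times drawing, for
#' every peptide, `n` of its replicas with replacement, averaging their
#' per-replica detachment scores into a peptide score, and computing the
#' AROC against the labels; report the standard deviation of the `B` AROC
#' values. Quantifies how many replicas are needed for a reliable
#' binder/non-binder call.
#'
#' @param replica_scores numeric matrix `[n_peptides, R]` of per-replica
#'   detachment scores (all peptides must share the replica count `R`)
#' @param labels per-peptide `binder` / `non-binder` labels
#' @param n_values replica counts to evaluate (each in `1..R`)
#' @param B bootstrap draws per `n` (default 5000)
#' @param seed RNG seed
#' @return data.frame with columns `n` and `sd_auroc`
#' @export
bootstrap_auroc_sd <- function(replica_scores, labels, n_values = c(1, 25, 100),
                               B = 5000L, seed = 1L) {
  replica_scores <- as.matrix(replica_scores)
  R <- ncol(replica_scores)
  P <- nrow(replica_scores)
  labels <- as.character(labels)
  if (length(labels) != P) stop("bootstrap_auroc_sd: labels do not match peptides")
  if (!all(c("binder", "non-binder") %in% labels))
    stop("bootstrap_auroc_sd: need both binder and non-binder labels")
  if (any(n_values < 1 | n_values > R))
    stop("bootstrap_auroc_sd: n_values must lie in 1..", R)
  set.seed(as.integer(seed))
  out <- vapply(n_values, function(n) {
    aucs <- vapply(seq_len(B), function(b) {
      idx <- matrix(sample.int(R, P * n, replace = TRUE), P, n)
      sc <- rowMeans(matrix(replica_scores[cbind(rep(seq_len(P), n), as.vector(idx))], P, n))
      auroc(sc, labels)
    }, numeric(1))
    stats::sd(aucs)
  }, numeric(1))
  data.frame(n = n_values, sd_auroc = out)
}

#' Per-replica detachment scores of a replica set
#'
#' Mean clamped probe distance per replica (over probes and snapshots);
#' the row vector consumed by [bootstrap_auroc_sd()].
#'
#' @inheritParams detachment_score
#' @return numeric vector, one score per replica
#' @export
replica_scores <- function(replicas, probes = c("N", "mid", "C"),
                           tail_frac = 1) {
  d <- replicas$distances[, , probes, drop = FALSE]
  ns <- dim(d)[2]
  keep <- seq.int(max(1L, ns - ceiling(tail_frac * ns) + 1L), ns)
  apply(d[, keep, , drop = FALSE], 1, mean)
}

#' Experimental binding records
#'
#' Builds/validates peptide binding labels. When only IC50 values are
#' given, peptides at or below the threshold are binders.
#'
#' @param sequence peptide sequences
#' @param class optional `binder` / `non-binder` labels
#' @param ic50 optional IC50 values, nM
#' @param threshold IC50 binder threshold, nM (default 500)
#' @return data.frame with columns `sequence`, `class`, `ic50`
#' @export
binding_records <- function(sequence, class = NULL, ic50 = NULL,
                            threshold = 500) {
  if (is.null(class) && is.null(ic50))
    stop("binding_records: need class labels or IC50 values")
  if (is.null(class)) class <- ifelse(ic50 <= threshold, "binder", "non-binder")
  class <- as.character(class)
  if (!all(class %in% c("binder", "non-binder")))
    stop("binding_records: class must be 'binder' or 'non-binder'")
  if (!is.null(ic50)) {
    implied <- ifelse(ic50 <= threshold, "binder", "non-binder")
    bad <- which(implied != class)
    if (length(bad))
      stop("binding_records: class inconsistent with IC50 at threshold ",
           threshold, " nM for: ", paste(sequence[bad], collapse = ", "))
  }
  data.frame(sequence = sequence, class = class,
             ic50 = if (is.null(ic50)) NA_real_ else ic50,
             stringsAsFactors = FALSE)
}
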