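# File formats: pair-potential tables, replica-set TSV, bead/trajectory
# PDB output, binding-label CSV. All plain text.

#' Write a pair potential to a plain-text table file
#'
#' Format: comment header, then `typing`, `bin_width`, `cutoff`,
#' `min_seq_sep`, `types` lines, then one `pair <type_i> <type_j> <e1>
#' ... <eN>` row per type pair with at least one non-zero bin (upper
#' triangle). Round-trips bit-exactly through [read_pair_potential()].
#'
#' @param pot [pair_potential()]
#' @param path output file
#' @export
write_pair_potential <- function(pot, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pair potential table (energies in k_B*T_ref, distances nm)",
               paste("typing", pot$typing),
               paste("bin_width", format(pot$bin_width, digits = 17)),
               paste("cutoff", format(pot$cutoff, digits = 17)),
               paste("min_seq_sep", pot$min_seq_sep),
               paste(c("types", pot$types), collapse = " ")), con)
  nt <- length(pot$types)
  for (i in seq_len(nt)) for (j in i:nt) {
    e <- pot$energies[i, j, ]
    if (all(e == 0)) next
    writeLines(paste(c("pair", pot$types[i], pot$types[j],
                       format(e, digits = 17, trim = TRUE, scientific = FALSE)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a pair potential from a plain-text table file
#' @param path file written by [write_pair_potential()] (or hand-authored
#'   in the same format)
#' @return [pair_potential()]
#' @export
read_pair_potential <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  kv <- function(key) {
    hit <- grep(paste0("^", key, "\\s"), ln, value = TRUE)
    if (!length(hit)) stop("read_pair_potential: missing '", key, "' line")
    strsplit(trimws(hit[1]), "\\s+")[[1]][-1]
  }
  typing <- kv("typing")
  bin_width <- as.numeric(kv("bin_width"))
  cutoff <- as.numeric(kv("cutoff"))
  min_sep <- as.integer(kv("min_seq_sep"))
  types <- kv("types")
  nb <- round(cutoff / bin_width)
  nt <- length(types)
  E <- array(0, c(nt, nt, nb))
  for (row in grep("^pair\\s", ln, value = TRUE)) {
    f <- strsplit(trimws(row), "\\s+")[[1]]
    i <- match(f[2], types); j <- match(f[3], types)
    if (is.na(i) || is.na(j)) stop("read_pair_potential: unknown type in row: ", row)
    e <- as.numeric(f[-(1:3)])
    if (length(e) != nb) stop("read_pair_potential: expected ", nb, " bins, got ", length(e))
    E[i, j, ] <- e
    E[j, i, ] <- e
  }
  pair_potential(types, E, bin_width, cutoff, min_seq_sep = min_sep,
                 typing = typing)
}

#' Write a replica set as tidy tab-separated text
#'
#' Long format, one row per (replica, step, probe): columns `peptide`,
#' `replica`, `step`, `probe`, `distance`.
#'
#' @param replicas [replica_set()]
#' @param path output file
#' @export
write_replica_set <- function(replicas, path) {
  d <- replicas$distances
  R <- dim(d)[1]; S <- dim(d)[2]
  df <- data.frame(
    peptide = replicas$peptide_id,
    replica = rep(seq_len(R), times = S * 3),
    step = rep(rep(replicas$steps, each = R), times = 3),
    probe = rep(dimnames(d)[[3]], each = R * S),
    distance = as.vector(d))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a replica set from tidy tab-separated text
#' @param path file written by [write_replica_set()]
#' @param ceiling clamp ceiling recorded with the set, nm
#' @param sequence optional peptide sequence
#' @return [replica_set()]
#' @export
read_replica_set <- function(path, ceiling = 3.0, sequence = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "replica", "step", "probe", "distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_replica_set: missing columns: ", paste(miss, collapse = ", "))
  steps <- sort(unique(df$step))
  reps <- sort(unique(df$replica))
  probes <- c("N", "mid", "C")
  d <- array(NA_real_, c(length(reps), length(steps), 3),
             dimnames = list(NULL, NULL, probes))
  for (p in 1:3) {
    sub <- df[df$probe == probes[p], ]
    d[cbind(match(sub$replica, reps), match(sub$step, steps), p)] <- sub$distance
  }
  if (anyNA(d)) stop("read_replica_set: replicas do not share one snapshot grid")
  replica_set(df$peptide[1], sequence, steps, d, ceiling = ceiling)
}

# fixed-format PDB ATOM line for a pseudo-atom bead
format_pdb_atom <- function(serial, name, resname, chain, resno, xyz_nm) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial %% 100000, name, resname, substr(chain, 1, 1), resno %% 10000,
          xyz_nm[1] * 10, xyz_nm[2] * 10, xyz_nm[3] * 10, 1, 0)
}

aa1to3 <- function(res1) {
  m <- stats::setNames(names(AA3TO1)[1:20], unname(AA3TO1[1:20]))
  out <- m[res1]
  out[is.na(out)] <- "UNK"
  out
}

#' Write a bead structure (or trajectory) as PDB
#'
#' Beads are written as pseudo-atoms named `CA`, `O` and `SC`; coordinates
#' are converted nm to Angstrom. With a snapshot array a multi-model PDB
#' (`MODEL`/`ENDMDL` per snapshot) is written.
#'
#' @param structure bead_structure (bead order/template)
#' @param path output file
#' @param snapshots optional array `[n_snap, n_beads, 3]` of coordinates
#'   (nm) from [run_mcmc()]
#' @export
write_beads_pdb <- function(structure, path, snapshots = NULL) {
  res3 <- aa1to3(structure$res)
  one_model <- function(co) {
    vapply(seq_len(nrow(structure)), function(i)
      format_pdb_atom(i, structure$kind[i], res3[i], structure$chain[i],
                      structure$resno[i], co[i, ]), character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(snapshots)) {
    writeLines(c(one_model(bead_coords(structure)), "END"), con)
  } else {
    for (s in seq_len(dim(snapshots)[1])) {
      writeLines(sprintf("MODEL     %4d", s), con)
      writeLines(one_model(matrix(snapshots[s, , ], ncol = 3)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Write the per-step log of a Monte Carlo trajectory
#'
#' Tab-separated: `step`, `energy`, `temperature`, `accepted`, `node`.
#'
#' @param trajectory from [run_mcmc()]
#' @param path output file
#' @export
write_mc_log <- function(trajectory, path) {
  df <- data.frame(step = trajectory$steps, energy = trajectory$energy,
                   temperature = trajectory$temperature,
                   accepted = as.integer(trajectory$accepted),
                   node = trajectory$node_labels[trajectory$node])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read experimental binding labels from CSV
#'
#' Two-column CSV: `sequence` plus either `class` (`binder`/`non-binder`)
#' or `ic50` / `IC50_nM` (nM; classified at the threshold).
#'
#' @param path CSV file
#' @param threshold IC50 binder threshold, nM
#' @return [binding_records()] data.frame
#' @export
read_binding_records <- function(path, threshold = 500) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  ic <- if ("ic50" %in% names(df)) df$ic50 else df[["ic50_nm"]]
  binding_records(df$sequence, class = df[["class"]], ic50 = ic,
                  threshold = threshold)
}
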