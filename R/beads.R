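#' Coarse-grained bead structures
#'
#' A `bead_structure` represents a protein in the 3-point-per-residue
#' coarse-grained model: every residue carries an alpha-carbon bead (`CA`),
#' a carbonyl-oxygen bead (`O`) and, for all residues except glycine, a
#' side-chain bead (`SC`) placed at the unweighted centroid of the
#' side-chain heavy atoms. Coordinates are stored in nanometres.
#'
#' The object is a `data.frame` with columns `chain`, `resno`, `res`
#' (one-letter code), `kind` (`"CA"`, `"O"` or `"SC"`), `type` (pair-potential
#' bead type label) and `x`, `y`, `z` (nm), carrying class
#' `"bead_structure"`. Beads of one residue are contiguous rows in the order
#' CA, O, SC; residues appear in increasing `resno` within each chain.
#'
#' @param df data.frame with the columns described above (`type` optional;
#'   filled by [default_bead_types()] when absent).
#' @param check validate invariants (bead completeness, glycine rule,
#'   virtual-bond sanity band). Default `TRUE`.
#' @return a `bead_structure`
#' @export
bead_structure <- function(df, check = TRUE) {
  needed <- c("chain", "resno", "res", "kind", "x", "y", "z")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("bead_structure: missing columns: ", paste(miss, collapse = ", "))
  df$chain <- as.character(df$chain)
  df$resno <- as.integer(df$resno)
  df$res <- as.character(df$res)
  df$kind <- as.character(df$kind)
  if (is.null(df$type)) df$type <- default_bead_types(df)
  df <- df[, c("chain", "resno", "res", "kind", "type", "x", "y", "z")]
  rownames(df) <- NULL
  class(df) <- c("bead_structure", "data.frame")
  if (check) validate_beads(df)
  df
}

#' Default pair-potential type labels for beads
#'
#' Backbone beads map to `"CA"` and `"O"`; side-chain beads to
#' `"SC_<one-letter residue code>"`, so that the potential can distinguish
#' side chains by residue type while sharing backbone parameters.
#'
#' @param df bead data.frame (columns `kind`, `res`)
#' @return character vector of type labels
#' @export
default_bead_types <- function(df) {
  ifelse(df$kind == "SC", paste0("SC_", df$res), df$kind)
}

# hard invariant checks; called from constructors
validate_beads <- function(x) {
  if (!all(is.finite(as.matrix(x[, c("x", "y", "z")]))))
    stop("bead_structure: non-finite coordinates")
  for (ch in unique(x$chain)) {
    cx <- x[x$chain == ch, ]
    resnos <- unique(cx$resno)
    if (is.unsorted(resnos, strictly = TRUE))
      stop("bead_structure: residue numbers not strictly increasing in chain ", ch)
    counts <- table(cx$resno, cx$kind)
    for (k in c("CA", "O")) {
      if (!k %in% colnames(counts) || any(counts[, k] != 1L))
        stop("bead_structure: chain ", ch, " has residues without exactly one ", k, " bead")
    }
    if ("SC" %in% colnames(counts) && any(counts[, "SC"] > 1L))
      stop("bead_structure: duplicated SC bead in chain ", ch)
    gly <- cx[cx$res == "G" & cx$kind == "SC", ]
    if (nrow(gly)) stop("bead_structure: glycine must not carry an SC bead (chain ", ch, ")")
    ca <- cx[cx$kind == "CA", c("x", "y", "z")]
    if (nrow(ca) > 1) {
      d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
      bad <- which(d < 0.2 | d > 0.6)
      if (length(bad))
        stop("bead_structure: chain ", ch, " consecutive CA-CA distance outside [0.2, 0.6] nm at residue index ",
             bad[1], " (", format(d[bad[1]], digits = 4), " nm)")
    }
  }
  invisible(x)
}

#' @export
print.bead_structure <- function(x, ...) {
  nres <- nrow(unique(as.data.frame(x)[, c("chain", "resno")]))
  cat("bead_structure:", nrow(x), "beads,", nres, "residues,",
      length(unique(x$chain)), "chain(s) [", paste(unique(x$chain), collapse = " "), "]\n")
  invisible(x)
}

#' Bead coordinates as a matrix
#' @param x bead_structure
#' @return numeric matrix (n_beads x 3), nm
#' @export
bead_coords <- function(x) {
  m <- as.matrix(as.data.frame(x)[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace bead coordinates
#' @param x bead_structure
#' @param coords numeric matrix (n_beads x 3), nm
#' @param check re-validate invariants
#' @return bead_structure with new coordinates
#' @export
set_bead_coords <- function(x, coords, check = FALSE) {
  stopifnot(nrow(coords) == nrow(x), ncol(coords) == 3)
  x$x <- coords[, 1]; x$y <- coords[, 2]; x$z <- coords[, 3]
  if (check) validate_beads(x)
  x
}

# per-residue table: chain, resno, res, ordinal within chain, row indices of beads
residue_table <- function(x) {
  key <- paste(x$chain, x$resno, sep = "\r")
  first <- !duplicated(key)
  rt <- data.frame(chain = x$chain[first], resno = x$resno[first],
                   res = x$res[first], stringsAsFactors = FALSE)
  rt$ord <- stats::ave(seq_len(nrow(rt)), rt$chain, FUN = seq_along)
  rt$ca_idx <- which(x$kind == "CA")
  rt$o_idx <- which(x$kind == "O")
  sc <- match(paste(rt$chain, rt$resno, sep = "\r"),
              ifelse(x$kind == "SC", key, NA))
  rt$sc_idx <- sc
  rt
}

# residue ordinal (position within its chain) per bead, plus chain index
bead_meta <- function(x) {
  chain_id <- match(x$chain, unique(x$chain))
  key <- paste(x$chain, x$resno, sep = "\r")
  rt_key <- unique(key)
  res_global <- match(key, rt_key)
  # ordinal within chain
  rt <- residue_table(x)
  ord <- rt$ord[res_global]
  list(chain = chain_id, ord = ord)
}

#' Chain sequence of a bead structure
#' @param x bead_structure
#' @param chain chain identifier
#' @return character scalar, one-letter codes
#' @export
chain_sequence <- function(x, chain) {
  rt <- residue_table(x)
  rt <- rt[rt$chain == chain, ]
  if (!nrow(rt)) stop("chain not found: ", chain)
  paste(rt$res, collapse = "")
}

#' Coarse-grain an all-atom PDB structure to the 3-point bead model
#'
#' Converts an all-atom protein model into the 3-point representation:
#' per residue a CA bead at the alpha-carbon, an O bead at the carbonyl
#' oxygen and an SC bead at the unweighted centroid of all side-chain heavy
#' atoms (Cbeta and beyond). Glycine gets no SC bead. Waters, ions, other
#' hetero-groups and hydrogens are discarded; alternate locations are
#' resolved by keeping the highest-occupancy copy. Coordinates are converted
#' from Angstrom to nanometres.
#'
#' @param pdb a `bio3d` `pdb` object (from [bio3d::read.pdb()]) or a path to
#'   a PDB file.
#' @param check validate bead-structure invariants after conversion
#'   (virtual-bond sanity band; disable for structures with chain breaks).
#' @return a [bead_structure()]
#' @export
coarse_grain_structure <- function(pdb, check = TRUE) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, rm.alt = FALSE, verbose = FALSE)
  if (!inherits(pdb, "pdb")) stop("coarse_grain_structure: need a bio3d pdb object or file path")
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("coarse_grain_structure: no ATOM records")
  # drop hydrogens (element column when present, else atom-name heuristic)
  if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy), keepNA = FALSE), na.rm = TRUE)) {
    at <- at[is.na(at$elesy) | !trimws(at$elesy) %in% c("H", "D"), , drop = FALSE]
  }
  at <- at[!grepl("^[0-9]*H", trimws(at$elety)), , drop = FALSE]
  # altloc: keep highest occupancy per (chain, resno, insert, atom name)
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  if (any(nzchar(alt))) {
    keykey <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert), at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(keykey, -occ)
    at <- at[ord, , drop = FALSE]
    dup <- duplicated(paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert), at$elety))
    if (any(dup)) {
      message("coarse_grain_structure: resolved ", sum(dup),
              " alternate location(s) by highest occupancy")
      at <- at[!dup, , drop = FALSE]
    }
    at <- at[order(match(rownames(at), rownames(pdb$atom))), , drop = FALSE]
  }
  ins <- ifelse(is.na(at$insert), "", trimws(at$insert))
  has_insert <- any(nzchar(ins))
  rid <- paste(at$chain, at$resno, ins, sep = "\r")
  ures <- unique(rid)
  rows <- vector("list", length(ures))
  renumber <- has_insert
  if (renumber) message("coarse_grain_structure: insertion codes present; residues renumbered sequentially per chain")
  ord_in_chain <- integer(0)
  chain_of <- sub("\r.*$", "", ures)
  ord_in_chain <- stats::ave(seq_along(ures), chain_of, FUN = seq_along)
  for (i in seq_along(ures)) {
    ra <- at[rid == ures[i], , drop = FALSE]
    ch <- ra$chain[1]
    resno <- if (renumber) ord_in_chain[i] else ra$resno[1]
    res3 <- toupper(trimws(ra$resid[1]))
    res1 <- if (res3 %in% names(AA3TO1)) AA3TO1[[res3]] else "X"
    nm <- trimws(ra$elety)
    ca <- ra[nm == "CA", , drop = FALSE]
    ox <- ra[nm == "O", , drop = FALSE]
    if (nrow(ca) != 1L)
      stop("coarse_grain_structure: missing CA in chain ", ch, " residue ", ra$resno[1])
    if (nrow(ox) != 1L)
      stop("coarse_grain_structure: missing carbonyl O in chain ", ch, " residue ", ra$resno[1])
    sc <- ra[!nm %in% BACKBONE_ATOMS, , drop = FALSE]
    out <- data.frame(
      chain = ch, resno = resno, res = res1,
      kind = c("CA", "O"),
      x = c(ca$x, ox$x) / 10, y = c(ca$y, ox$y) / 10, z = c(ca$z, ox$z) / 10,
      stringsAsFactors = FALSE)
    if (res1 != "G") {
      if (nrow(sc)) {
        out <- rbind(out, data.frame(
          chain = ch, resno = resno, res = res1, kind = "SC",
          x = mean(sc$x) / 10, y = mean(sc$y) / 10, z = mean(sc$z) / 10,
          stringsAsFactors = FALSE))
      } else {
        message("coarse_grain_structure: no side-chain heavy atoms for chain ",
                ch, " residue ", resno, "; treated as glycine")
        out$res <- "G"
      }
    }
    rows[[i]] <- out
  }
  bead_structure(do.call(rbind, rows), check = check)
}

#' Thread a new peptide sequence onto a template chain
#'
#' Replaces the sequence of one chain while keeping the backbone beads (CA,
#' O) fixed. Each side-chain bead is repositioned along the template's
#' CA->SC unit vector at the canonical CA-SC distance of the new residue
#' type (packaged table [CA_SC_DIST]); mutating to glycine removes the SC
#' bead, and `X` is treated as glycine. When the template residue has no SC
#' bead (glycine) the direction is rebuilt from the local backbone: the unit
#' vector from the midpoint of the flanking CA beads to the residue's CA
#' (at a terminus, the CA->O direction is used instead).
#'
#' @param template bead_structure
#' @param chain chain identifier of the peptide chain to re-thread
#' @param new_sequence character scalar of one-letter codes, same length as
#'   the chain
#' @return bead_structure with the threaded sequence
#' @export
thread_peptide <- function(template, chain, new_sequence) {
  rt <- residue_table(template)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (!nrow(rt)) stop("thread_peptide: chain not found: ", chain)
  seq_new <- strsplit(toupper(new_sequence), "")[[1]]
  if (length(seq_new) != nrow(rt))
    stop("thread_peptide: sequence length ", length(seq_new),
         " does not match chain length ", nrow(rt))
  bad <- setdiff(seq_new, c(AA1, "X"))
  if (length(bad)) stop("thread_peptide: unknown residue code(s): ", paste(bad, collapse = ", "))
  seq_new[seq_new == "X"] <- "G"
  df <- as.data.frame(template)
  drop_rows <- integer(0)
  add_rows <- list()
  for (i in seq_len(nrow(rt))) {
    aa <- seq_new[i]
    if (aa == rt$res[i]) next   # unchanged residue: bead-for-bead identity
    ca <- as.numeric(df[rt$ca_idx[i], c("x", "y", "z")])
    sc_idx <- rt$sc_idx[i]
    res_rows <- which(df$chain == chain & df$resno == rt$resno[i])
    df$res[res_rows] <- aa
    if (aa == "G") {
      if (!is.na(sc_idx)) drop_rows <- c(drop_rows, sc_idx)
      next
    }
    if (!is.na(sc_idx)) {
      u <- as.numeric(df[sc_idx, c("x", "y", "z")]) - ca
    } else {
      # rebuild a pseudo side-chain direction from the backbone
      if (i > 1 && i < nrow(rt)) {
        mid <- (as.numeric(df[rt$ca_idx[i - 1], c("x", "y", "z")]) +
                as.numeric(df[rt$ca_idx[i + 1], c("x", "y", "z")])) / 2
        u <- ca - mid
      } else {
        u <- ca - as.numeric(df[rt$o_idx[i], c("x", "y", "z")])
      }
    }
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) stop("thread_peptide: degenerate side-chain direction at residue ", rt$resno[i])
    pos <- ca + u / nu * CA_SC_DIST[[aa]]
    if (!is.na(sc_idx)) {
      df[sc_idx, c("x", "y", "z")] <- as.list(pos)
      df$res[sc_idx] <- aa
    } else {
      add_rows[[length(add_rows) + 1L]] <- data.frame(
        chain = chain, resno = rt$resno[i], res = aa, kind = "SC",
        type = NA_character_, x = pos[1], y = pos[2], z = pos[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(drop_rows)) df <- df[-drop_rows, , drop = FALSE]
  if (length(add_rows)) df <- rbind(df, do.call(rbind, add_rows))
  # restore canonical bead order: chain blocks as before, residues ascending, CA/O/SC
  chains <- unique(df$chain)
  kind_rank <- match(df$kind, c("CA", "O", "SC"))
  df <- df[order(match(df$chain, chains), df$resno, kind_rank), , drop = FALSE]
  df$type <- default_bead_types(df)
  bead_structure(df, check = FALSE)
}
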