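#' Regions and region hierarchies for natural moves
#'
#' A *region* is a contiguous stretch of residues of one chain that is moved
#' as a rigid body (a natural move). Regions can be grouped into
#' *super-regions* (for example the two kink-broken halves of an MHC helix
#' under the whole helix). The hierarchy is a forest of such nodes; every
#' node carries rigid-body move amplitudes (maximum translation in nm,
#' maximum rotation in degrees) and a selection weight.
#'
#' @param chain chain identifier
#' @param from,to inclusive residue-number range (author numbering)
#' @param label node label
#' @return for `region()`, a node description usable in [region_hierarchy()]
#' @export
region <- function(chain, from, to, label = sprintf("%s:%d-%d", chain, from, to)) {
  if (to < from) stop("region: empty range ", from, "..", to)
  list(label = label, chain = chain, ranges = cbind(from = from, to = to))
}

# internal node constructor; ranges: 2-col matrix (from, to), possibly multi-row
new_node <- function(label, chain, ranges, parent = NA_integer_,
                     max_trans = 0.05, max_rot = 5, weight = 1) {
  ranges <- rbind(ranges)
  if (any(ranges[, 2] < ranges[, 1])) stop("region '", label, "': empty residue range")
  list(label = label, chain = chain, ranges = ranges, parent = parent,
       max_trans = max_trans, max_rot = max_rot, weight = weight)
}

ranges_to_set <- function(ranges) {
  unlist(lapply(seq_len(nrow(ranges)), function(i) ranges[i, 1]:ranges[i, 2]))
}

#' Assemble and validate a region hierarchy
#'
#' @param nodes list of nodes as built by [region()]/internal helpers; each
#'   may carry a `parent` index into the same list.
#' @param structure optional [bead_structure()] used to check that every
#'   region lies within its chain.
#' @return object of class `region_hierarchy`
#' @export
region_hierarchy <- function(nodes, structure = NULL) {
  if (!length(nodes)) stop("region_hierarchy: need at least one node")
  for (i in seq_along(nodes)) {
    n <- nodes[[i]]
    if (is.null(n$parent)) nodes[[i]]$parent <- NA_integer_
    if (is.null(n$max_trans)) nodes[[i]]$max_trans <- 0.05
    if (is.null(n$max_rot)) nodes[[i]]$max_rot <- 5
    if (is.null(n$weight)) nodes[[i]]$weight <- 1
  }
  h <- structure(list(nodes = nodes), class = "region_hierarchy")
  validate_hierarchy(h, structure)
  h
}

validate_hierarchy <- function(h, struc = NULL) {
  nodes <- h$nodes
  res_tab <- if (!is.null(struc)) residue_table(struc) else NULL
  sets <- lapply(nodes, function(n) paste(n$chain, ranges_to_set(n$ranges)))
  for (i in seq_along(nodes)) {
    n <- nodes[[i]]
    if (!is.null(res_tab)) {
      avail <- res_tab$resno[res_tab$chain == n$chain]
      missing <- setdiff(ranges_to_set(n$ranges), avail)
      if (length(missing))
        stop("region '", n$label, "': residues not in chain ", n$chain, ": ",
             paste(utils::head(missing, 5), collapse = ","))
    }
    p <- n$parent
    if (!is.na(p)) {
      if (p < 1 || p > length(nodes)) stop("region '", n$label, "': bad parent index")
      if (!all(sets[[i]] %in% sets[[p]]))
        stop("region '", n$label, "': residues not a subset of parent '", nodes[[p]]$label, "'")
    }
  }
  # sibling leaves must not overlap
  for (p in seq_along(nodes)) {
    kids <- which(vapply(nodes, function(n) identical(n$parent, p) ||
                           (!is.na(n$parent) && n$parent == p), logical(1)))
    if (length(kids) > 1) {
      all_res <- unlist(sets[kids])
      if (anyDuplicated(all_res))
        stop("region hierarchy: children of '", nodes[[p]]$label, "' overlap")
    }
  }
  invisible(h)
}

#' @export
print.region_hierarchy <- function(x, ...) {
  cat("region_hierarchy with", length(x$nodes), "node(s):\n")
  for (i in seq_along(x$nodes)) {
    n <- x$nodes[[i]]
    pad <- if (is.na(n$parent)) "" else "  "
    rng <- paste(apply(n$ranges, 1, function(r) paste0(r[1], "-", r[2])), collapse = ",")
    cat(sprintf("%s[%d] %-18s chain %s res %s (t<=%.3g nm, rot<=%.3g deg, w=%.3g)\n",
                pad, i, n$label, n$chain, rng, n$max_trans, n$max_rot, n$weight))
  }
  invisible(x)
}

#' Number of hierarchy nodes belonging to one chain
#' @param h region_hierarchy
#' @param chain chain identifier
#' @return integer node count
#' @export
chain_node_count <- function(h, chain) {
  sum(vapply(h$nodes, function(n) n$chain == chain, logical(1)))
}

#' Residue numbers covered by a hierarchy node
#' @param h region_hierarchy
#' @param id node index
#' @return integer vector of residue numbers
#' @export
node_residues <- function(h, id) sort(ranges_to_set(h$nodes[[id]]$ranges))

#' Build the standard pMHC region hierarchy
#'
#' Decomposes a peptide-MHC complex into the natural-move regions used for
#' detachment simulations. The MHC alpha1/alpha2 groove domain yields exactly
#' seven nodes: the beta-sheet floor (one leaf, possibly spanning several
#' sequence segments), and for each of the two groove helices a whole-helix
#' super-region with two kink-broken leaf regions beneath it. The peptide
#' chain yields a whole-peptide super-region over leaf sub-regions (default
#' residues 1-3, 4-6, 7-9 for a 9-mer). Residues outside the groove domain
#' (alpha3, beta2-microglobulin) are assigned to no region and stay fixed;
#' they still contribute to the energy.
#'
#' @param structure bead_structure of the complex
#' @param config list (or path to a YAML file) with keys `mhc_chain`,
#'   `peptide_chain`, `helix1_range`, `helix1_kink`, `helix2_range`,
#'   `helix2_kink`; optional `mhc_range` (groove domain span, default whole
#'   chain), `peptide_subregions` (list of `c(from, to)`), `max_trans` (nm,
#'   default 0.05), `max_rot` (degrees, default 5), `peptide_scale`
#'   (amplitude multiplier for the whole-peptide node, default 2).
#' @return region_hierarchy
#' @export
build_pmhc_hierarchy <- function(structure, config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("mhc_chain", "peptide_chain", "helix1_range", "helix1_kink",
            "helix2_range", "helix2_kink")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("build_pmhc_hierarchy: missing config keys: ", paste(miss, collapse = ", "))
  mhc <- config$mhc_chain; pep <- config$peptide_chain
  rt <- residue_table(structure)
  mres <- rt$resno[rt$chain == mhc]
  pres <- rt$resno[rt$chain == pep]
  if (!length(mres)) stop("build_pmhc_hierarchy: MHC chain not found: ", mhc)
  if (!length(pres)) stop("build_pmhc_hierarchy: peptide chain not found: ", pep)
  mhc_range <- if (!is.null(config$mhc_range)) as.integer(config$mhc_range) else range(mres)
  h1 <- as.integer(config$helix1_range); k1 <- as.integer(config$helix1_kink)
  h2 <- as.integer(config$helix2_range); k2 <- as.integer(config$helix2_kink)
  tmax <- config$max_trans %||% 0.05
  rmax <- config$max_rot %||% 5
  pscale <- config$peptide_scale %||% 2
  if (max(h1[1], h2[1]) <= min(h1[2], h2[2]))
    stop("build_pmhc_hierarchy: helix ranges overlap")
  for (hr in list(c(h1, k1), c(h2, k2))) {
    if (hr[3] <= hr[1] || hr[3] > hr[2])
      stop("build_pmhc_hierarchy: kink at residue ", hr[3],
           " outside the splittable interior of helix ", hr[1], "-", hr[2])
  }
  helices <- sort(c(h1, h2))
  # floor = groove domain minus the two helices
  floor_ranges <- NULL
  cur <- mhc_range[1]
  for (hr in list(sort(c(h1[1], h1[2])), sort(c(h2[1], h2[2])))[order(c(h1[1], h2[1]))]) {
    if (cur < hr[1]) floor_ranges <- rbind(floor_ranges, c(cur, hr[1] - 1L))
    cur <- hr[2] + 1L
  }
  if (cur <= mhc_range[2]) floor_ranges <- rbind(floor_ranges, c(cur, mhc_range[2]))
  if (is.null(floor_ranges)) stop("build_pmhc_hierarchy: no floor residues left in mhc_range")
  # peptide sub-regions
  subs <- config$peptide_subregions
  if (is.null(subs)) subs <- default_subregions(pres)
  subs <- lapply(subs, as.integer)
  all_sub <- unlist(lapply(subs, function(r) r[1]:r[2]))
  if (anyDuplicated(all_sub)) stop("build_pmhc_hierarchy: peptide sub-regions overlap")

  nodes <- list()
  nodes[[1]] <- new_node("mhc_floor", mhc, floor_ranges, max_trans = tmax, max_rot = rmax)
  nodes[[2]] <- new_node("helix1", mhc, c(h1[1], h1[2]), max_trans = tmax, max_rot = rmax)
  nodes[[3]] <- new_node("helix1_n", mhc, c(h1[1], k1 - 1L), parent = 2L, max_trans = tmax, max_rot = rmax)
  nodes[[4]] <- new_node("helix1_c", mhc, c(k1, h1[2]), parent = 2L, max_trans = tmax, max_rot = rmax)
  nodes[[5]] <- new_node("helix2", mhc, c(h2[1], h2[2]), max_trans = tmax, max_rot = rmax)
  nodes[[6]] <- new_node("helix2_n", mhc, c(h2[1], k2 - 1L), parent = 5L, max_trans = tmax, max_rot = rmax)
  nodes[[7]] <- new_node("helix2_c", mhc, c(k2, h2[2]), parent = 5L, max_trans = tmax, max_rot = rmax)
  nodes[[8]] <- new_node("peptide", pep, range(pres),
                         max_trans = pscale * tmax, max_rot = pscale * rmax)
  for (i in seq_along(subs)) {
    nodes[[8L + i]] <- new_node(paste0("pep_sub", i), pep, subs[[i]], parent = 8L,
                                max_trans = tmax, max_rot = rmax)
  }
  region_hierarchy(nodes, structure)
}

# default peptide split into three near-equal contiguous sub-regions
default_subregions <- function(resnos) {
  L <- length(resnos)
  if (L < 3) return(list(range(resnos)))
  cuts <- round(seq(0, L, length.out = 4))
  lapply(1:3, function(i) c(resnos[cuts[i] + 1L], resnos[cuts[i + 1L]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
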