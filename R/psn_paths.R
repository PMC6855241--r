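# Protein structure networks, dynamic cross-correlation and
# correlation-filtered communication pathways between pockets.

#' Structure-network configuration
#'
#' @param distance_cutoff side-chain atom-pair distance cutoff in Angstrom
#'   (default 4.5, the conventional structure-network value).
#' @param i_min interaction-percentage cutoff for an edge (percent). The
#'   value is a free parameter of the method; 3.0 is a common choice and is
#'   always echoed in pipeline reports.
#' @param normalization `"uniform"` (every residue type gets N = 100, making
#'   the interaction percentage a scaled pair count) or `"table"` (per
#'   residue-type values supplied in `norm_table`).
#' @param norm_table named numeric vector, residue type -> normalization
#'   factor; required in `"table"` mode.
#' @param normalization_product divide by the product `N_i * N_j` instead of
#'   the usual `sqrt(N_i * N_j)`.
#' @param exclude_bonded drop sequence-adjacent residue pairs (same chain,
#'   consecutive numbering) from edges? Default `TRUE`; such contacts are
#'   trivial backbone neighbours.
#' @param include_hydrogens count hydrogen atoms in side-chain pairs
#'   (default `FALSE`, heavy atoms only).
#' @param gly_calpha treat the glycine C-alpha as its side chain (default
#'   `TRUE`), so glycines can still form network edges.
#' @return list of class `psn_config`.
#' @export
psn_config <- function(distance_cutoff = 4.5, i_min = 3.0,
                       normalization = c("uniform", "table"),
                       norm_table = NULL, normalization_product = FALSE,
                       exclude_bonded = TRUE, include_hydrogens = FALSE,
                       gly_calpha = TRUE) {
  normalization <- match.arg(normalization)
  stopifnot(distance_cutoff > 0, i_min >= 0)
  if (normalization == "table" && is.null(norm_table))
    stop("normalization = 'table' requires norm_table")
  structure(list(distance_cutoff = distance_cutoff, i_min = i_min,
                 normalization = normalization, norm_table = norm_table,
                 normalization_product = normalization_product,
                 exclude_bonded = exclude_bonded,
                 include_hydrogens = include_hydrogens,
                 gly_calpha = gly_calpha),
            class = "psn_config")
}

# Indices of atoms that count as "side chain" for pair counting.
sidechain_mask <- function(topology, config) {
  backbone <- topology$atom_name %in% c("N", "CA", "C", "O", "OXT")
  mask <- !backbone
  if (config$gly_calpha)
    mask <- mask | (topology$residue_name == "GLY" & topology$atom_name == "CA")
  if (!config$include_hydrogens) mask <- mask & topology$element != "H"
  mask & topology$record == "ATOM"
}

#' Residue interaction matrix for one frame
#'
#' For every residue pair, `n_ij` counts side-chain atom pairs within the
#' distance cutoff and the interaction percentage is
#' `I_ij = 100 * n_ij / sqrt(N_i * N_j)` (or the product form if configured).
#' Sequence-adjacent pairs are zeroed when `exclude_bonded` is set.
#'
#' @param ens an [ensemble].
#' @param frame frame index.
#' @param config a [psn_config].
#' @return list of class `interaction_matrix` with `I` (percent), `n`
#'   (pair counts), `residues` (residue keys), `config`.
#' @export
interaction_matrix <- function(ens, frame = 1L, config = psn_config()) {
  stopifnot(inherits(ens, "ensemble"), inherits(config, "psn_config"))
  topo <- ens$topology
  res <- residue_table(topo)
  keys <- res$key
  nres <- length(keys)
  if (config$normalization == "table") {
    missing <- setdiff(unique(res$residue_name), names(config$norm_table))
    if (length(missing) > 0L)
      stop("normalization table lacks residue type(s): ",
           paste(missing, collapse = ", "))
    nvals <- config$norm_table[res$residue_name]
  } else {
    nvals <- rep(100, nres)
  }
  mask <- which(sidechain_mask(topo, config))
  n_mat <- matrix(0L, nres, nres, dimnames = list(keys, keys))
  if (length(mask) >= 2L) {
    xyz <- get_frame(ens, frame)[mask, , drop = FALSE]
    atom_res <- match(atom_residue_keys(topo)[mask], keys)
    d <- as.matrix(stats::dist(xyz))
    hit <- which(d <= config$distance_cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      ri <- atom_res[hit[, 1L]]
      rj <- atom_res[hit[, 2L]]
      keep <- ri != rj
      if (any(keep)) {
        a <- pmin(ri[keep], rj[keep])
        b <- pmax(ri[keep], rj[keep])
        tab <- table(paste(a, b))
        ij <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
        n_mat[ij] <- as.integer(tab)
        n_mat[ij[, c(2L, 1L), drop = FALSE]] <- as.integer(tab)
      }
    }
  }
  if (config$exclude_bonded) {
    same_chain <- outer(res$chain_id, res$chain_id, `==`)
    seq_adj <- abs(outer(res$residue_number, res$residue_number, `-`)) == 1L &
      same_chain & outer(res$insertion_code == "", res$insertion_code == "", `&`)
    n_mat[seq_adj] <- 0L
  }
  denom <- if (config$normalization_product) outer(nvals, nvals)
           else sqrt(outer(nvals, nvals))
  i_mat <- 100 * n_mat / denom
  diag(i_mat) <- 0
  diag(n_mat) <- 0L
  structure(list(I = i_mat, n = n_mat, residues = keys, config = config),
            class = "interaction_matrix")
}

#' Build a structure-network graph from an interaction matrix
#'
#' Residues are nodes; an undirected edge joins residues with
#' `I_ij >= i_min` and at least one contacting atom pair. Edge weights carry
#' the interaction percentage. Isolated residues stay in the graph so pocket
#' lookups never fail on a contact-free residue.
#'
#' @param im an [interaction_matrix()].
#' @param config a [psn_config] (defaults to the one the matrix was built
#'   with).
#' @return an `igraph` graph with vertex attribute `name` (residue key) and
#'   edge attributes `I` and `n`.
#' @export
build_psn <- function(im, config = im$config) {
  stopifnot(inherits(im, "interaction_matrix"))
  keep <- im$I >= config$i_min & im$n >= 1L & upper.tri(im$I)
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(im$residues), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = im$residues)
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "I", value = im$I[idx])
    g <- igraph::set_edge_attr(g, "n", value = im$n[idx])
  }
  g
}

#' Per-frame structure networks for a whole ensemble
#'
#' @param ens an [ensemble].
#' @param config a [psn_config].
#' @return list of `igraph` graphs, one per frame.
#' @export
psn_per_frame <- function(ens, config = psn_config()) {
  lapply(seq_len(n_frames(ens)), function(f)
    build_psn(interaction_matrix(ens, f, config), config))
}

#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of per-residue displacement vectors over the
#' ensemble: `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, values in
#' [-1, 1]. Frames are optionally superposed onto the ensemble mean (two
#' refinement passes) first, which removes rigid-body motion. Residues with
#' zero displacement variance are flagged and their rows/columns zeroed;
#' path filtering ignores them.
#'
#' @param ens an [ensemble] with >= 2 frames.
#' @param atom_sel integer atom indices, one atom per residue (default: all
#'   C-alpha atoms).
#' @param superpose superpose frames onto the iterated mean first?
#' @return residue x residue matrix of class `dcc_matrix` with residue keys
#'   as dimnames and attribute `flagged` (keys with zero variance).
#' @export
dcc_matrix <- function(ens, atom_sel = NULL, superpose = TRUE) {
  stopifnot(inherits(ens, "ensemble"))
  nf <- n_frames(ens)
  if (nf < 2L) stop("dynamic cross-correlation needs at least 2 frames")
  topo <- ens$topology
  if (is.null(atom_sel)) atom_sel <- which(topo$atom_name == "CA")
  if (length(atom_sel) == 0L) stop("empty atom selection")
  keys <- atom_residue_keys(topo)[atom_sel]
  coords <- array(NA_real_, dim = c(nf, length(atom_sel), 3L))
  for (t in seq_len(nf)) coords[t, , ] <- get_frame(ens, t)[atom_sel, , drop = FALSE]
  if (superpose) {
    for (pass in 1:2) {
      mean_xyz <- apply(coords, c(2L, 3L), mean)
      for (t in seq_len(nf))
        coords[t, , ] <- kabsch_superpose(coords[t, , ], mean_xyz)$coords
    }
  }
  mean_xyz <- apply(coords, c(2L, 3L), mean)
  for (t in seq_len(nf)) coords[t, , ] <- coords[t, , ] - mean_xyz
  # <dr_i . dr_j> summed over axes
  cov_ij <- matrix(0, length(atom_sel), length(atom_sel))
  for (ax in 1:3) cov_ij <- cov_ij + crossprod(coords[, , ax]) / nf
  v <- diag(cov_ij)
  flagged <- v < 1e-12
  if (all(flagged)) warning("all residues have zero variance (identical frames)")
  denom <- sqrt(outer(pmax(v, 1e-300), pmax(v, 1e-300)))
  c_mat <- cov_ij / denom
  c_mat[flagged, ] <- 0
  c_mat[, flagged] <- 0
  dg <- diag(c_mat)
  dg[!flagged] <- 1
  diag(c_mat) <- dg
  c_mat <- pmin(pmax(c_mat, -1), 1)
  dimnames(c_mat) <- list(keys, keys)
  attr(c_mat, "flagged") <- keys[flagged]
  class(c_mat) <- c("dcc_matrix", class(c_mat))
  c_mat
}

# order two path candidates: fewer hops, then larger summed I, then
# lexicographically smaller residue sequence (by chain, number, icode)
path_before <- function(a, b) {
  if (length(a$path) != length(b$path)) return(length(a$path) < length(b$path))
  if (abs(a$sum_I - b$sum_I) > 1e-9) return(a$sum_I > b$sum_I)
  ka <- residue_sort_keys(a$path); kb <- residue_sort_keys(b$path)
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return(TRUE)
    if (ka[i] > kb[i]) return(FALSE)
  }
  FALSE
}

# drop PSN edges whose endpoints are not correlated enough
filter_graph_by_dcc <- function(graph, dcc, corr_min) {
  if (is.null(dcc) || corr_min <= 0) return(graph)
  el <- igraph::as_edgelist(graph)
  if (nrow(el) == 0L) return(graph)
  known <- el[, 1L] %in% rownames(dcc) & el[, 2L] %in% rownames(dcc)
  cvals <- rep(0, nrow(el))
  cvals[known] <- abs(dcc[cbind(el[known, 1L], el[known, 2L])])
  igraph::delete_edges(graph, which(cvals < corr_min))
}

#' Correlation-filtered shortest communication path
#'
#' Searches the structure network restricted to edges whose endpoints move
#' in a correlated way (`|C_ij| >= corr_min`) for a minimum-hop path from
#' `source` to `sink`. Among equal-hop paths the one with the largest summed
#' interaction percentage wins; remaining ties go to the lexicographically
#' smallest residue sequence, so the result is deterministic.
#'
#' @param graph a structure network from [build_psn()].
#' @param source,sink residue keys (`"A:195"` style).
#' @param dcc optional [dcc_matrix()]; `NULL` disables correlation
#'   filtering.
#' @param corr_min minimum `|C_ij|` for an edge to be traversable
#'   (default 0.3, a free parameter of the method).
#' @return `NULL` if disconnected, otherwise a list of class `psn_path`:
#'   `path` (residue keys), `hops`, `sum_I`, `mean_abs_C`.
#' @export
shortest_path <- function(graph, source, sink, dcc = NULL, corr_min = 0.3) {
  vn <- igraph::V(graph)$name
  if (!source %in% vn) stop("source residue not in graph: ", source)
  if (!sink %in% vn) stop("sink residue not in graph: ", sink)
  if (source == sink)
    return(structure(list(path = source, hops = 0L, sum_I = 0,
                          mean_abs_C = NA_real_), class = "psn_path"))
  g <- filter_graph_by_dcc(graph, dcc, corr_min)
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = source, to = sink))$vpaths
  if (length(sp) == 0L) return(NULL)
  cands <- lapply(sp, function(vp) {
    p <- igraph::as_ids(vp)
    eids <- igraph::get_edge_ids(g, as.vector(rbind(p[-length(p)], p[-1L])))
    list(path = p, hops = length(p) - 1L,
         sum_I = sum(igraph::E(g)$I[eids]),
         mean_abs_C = if (is.null(dcc)) NA_real_
                      else mean(abs(dcc[cbind(p[-length(p)], p[-1L])])))
  })
  best <- cands[[1L]]
  for (cand in cands[-1L]) if (path_before(cand, best)) best <- cand
  structure(best, class = "psn_path")
}

#' @export
print.psn_path <- function(x, ...) {
  cat(paste(x$path, collapse = " - "), "\n")
  cat("hops:", x$hops, " summed I:", round(x$sum_I, 2), "\n")
  invisible(x)
}

#' Tally communication pathways between two pockets across frames
#'
#' For every frame and every (source, sink) residue pair, the
#' correlation-filtered shortest path is computed; identical residue
#' sequences are pooled and each path's frequency is the fraction of frames
#' supporting it (a path counts once per frame even if several pocket pairs
#' produce it). Reported alongside: the number of distinct paths at or above
#' `freq_min` and the single highest-frequency path.
#'
#' @param graphs list of per-frame structure networks ([psn_per_frame()]).
#' @param sources,sinks [residue_selection]s or character vectors of residue
#'   keys for the two pockets.
#' @param dcc optional [dcc_matrix()] for correlation filtering.
#' @param corr_min edge correlation threshold (default 0.3).
#' @param freq_min frequency threshold for the headline count
#'   (default 0.30, i.e. a pathway must recur in at least 30% of frames).
#' @return object of class `path_tally`: data.frame (`path`, `hops`,
#'   `frequency`) sorted by frequency, with attributes `n_above`,
#'   `top_path`, `n_frames`, `freq_min`.
#' @export
tally_paths <- function(graphs, sources, sinks, dcc = NULL, corr_min = 0.3,
                        freq_min = 0.30) {
  if (length(graphs) < 1L) stop("need at least one frame graph")
  as_keys <- function(x)
    if (inherits(x, "residue_selection")) selection_keys(x) else as.character(x)
  src <- as_keys(sources); snk <- as_keys(sinks)
  if (length(src) == 0L || length(snk) == 0L) stop("empty pocket selection")
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (g in graphs) {
    seen <- character(0)
    for (s in src) for (t in snk) {
      p <- shortest_path(g, s, t, dcc = dcc, corr_min = corr_min)
      if (is.null(p) || p$hops == 0L) next
      id <- paste(p$path, collapse = "->")
      if (id %in% seen) next
      seen <- c(seen, id)
      counts[[id]] <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
      meta[[id]] <- p
    }
  }
  ids <- ls(counts)
  nf <- length(graphs)
  df <- data.frame(path = ids,
                   hops = vapply(ids, function(i) meta[[i]]$hops, 0L),
                   frequency = vapply(ids, function(i) counts[[i]], 0L) / nf,
                   stringsAsFactors = FALSE)
  ord <- order(-df$frequency, df$hops, df$path)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_above") <- sum(df$frequency >= freq_min)
  attr(df, "top_path") <- if (nrow(df) > 0L) strsplit(df$path[1L], "->",
                                                      fixed = TRUE)[[1L]]
  attr(df, "n_frames") <- nf
  attr(df, "freq_min") <- freq_min
  class(df) <- c("path_tally", "data.frame")
  df
}

#' @export
print.path_tally <- function(x, ...) {
  cat("Communication pathways over", attr(x, "n_frames"), "frame(s):",
      nrow(x), "distinct,", attr(x, "n_above"),
      sprintf("at frequency >= %.0f%%\n", 100 * attr(x, "freq_min")))
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(as.data.frame(x), 10L))
  }
  invisible(x)
}
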