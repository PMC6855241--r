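# Synthetic ensembles, score sets and energy tables with analytic ground
# truth. These generators stand in for the MD and docking engines so every
# downstream stage can be tested against a known answer.

# Pseudo-atom topology builder: one row per atom.
pseudo_topology <- function(chain_id, residue_number, atom_name, element,
                            residue_name = "ALA") {
  n <- length(chain_id)
  data.frame(serial = seq_len(n),
             atom_name = atom_name,
             element = element,
             residue_name = rep_len(residue_name, n),
             chain_id = chain_id,
             residue_number = residue_number,
             insertion_code = "",
             occupancy = 1,
             altloc = "",
             record = "ATOM",
             stringsAsFactors = FALSE)
}

# Ideal alpha-helical C-alpha trace: radius 2.3 A, rise 1.5 A, 100 deg/residue
# gives consecutive C-alpha spacing ~3.8 A and a self-avoiding curve.
helix_trace <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta) + origin[1L],
        2.3 * sin(theta) + origin[2L],
        1.5 * i + origin[3L])
}

#' Gaussian-network-model ensemble with analytic correlations
#'
#' Builds a self-avoiding C-alpha trace (one pseudo-atom per residue, helical
#' geometry; a second chain, if requested, is offset so the two are in
#' contact), forms the Kirchhoff connectivity matrix at the contact cutoff,
#' and samples frames from the zero-mean Gaussian whose per-axis covariance
#' is `scale` times the Kirchhoff pseudo-inverse. The analytic residue
#' correlation matrix implied by that covariance is attached as ground truth,
#' which is what makes this generator an oracle for dynamic cross-correlation
#' analysis.
#'
#' @param n_residues residues per chain.
#' @param n_frames number of frames to sample (>= 2).
#' @param n_chains 1 or 2.
#' @param cutoff contact cutoff in Angstrom for the Kirchhoff matrix
#'   (default 8, the usual coarse-grained elastic-network choice).
#' @param scale fluctuation scale in Angstrom^2 (>= 0); 0 gives a rigid
#'   ensemble equal to the mean structure.
#' @param seed integer seed; identical seeds give bit-identical frames.
#' @return an [ensemble] with attributes `correlation` (analytic residue
#'   correlation matrix, residue keys as dimnames) and `covariance`.
#' @export
make_gnm_ensemble <- function(n_residues, n_frames, n_chains = 1L,
                              cutoff = 8, scale = 1, seed = 1L) {
  stopifnot(n_frames >= 2L, scale >= 0, cutoff > 0, n_chains %in% c(1L, 2L))
  coords <- helix_trace(n_residues)
  chains <- rep("A", n_residues)
  if (n_chains == 2L) {
    coords <- rbind(coords, helix_trace(n_residues, origin = c(cutoff - 1, 0, 0)))
    chains <- c(chains, rep("B", n_residues))
  }
  n <- nrow(coords)
  topo <- pseudo_topology(chains, rep(seq_len(n_residues), n_chains),
                          "CA", "C")
  d <- as.matrix(stats::dist(coords))
  adj <- d <= cutoff & upper.tri(d)
  k_mat <- matrix(0, n, n)
  k_mat[adj] <- -1
  k_mat <- k_mat + t(k_mat)
  diag(k_mat) <- -rowSums(k_mat)

  eg <- eigen(k_mat, symmetric = TRUE)
  tol <- 1e-8 * max(eg$values, 1)
  zero_modes <- sum(eg$values < tol)
  if (zero_modes > 1L)
    stop("disconnected contact graph (", zero_modes, " zero modes); ",
         "increase the contact cutoff")
  keep <- eg$values >= tol
  v <- eg$vectors[, keep, drop = FALSE]
  lambda <- eg$values[keep]
  covm <- scale * v %*% (t(v) / lambda)
  sdv <- sqrt(pmax(diag(covm), 0))
  corr <- covm / outer(sdv, sdv)
  diag(corr) <- 1
  keys <- atom_residue_keys(topo)
  dimnames(corr) <- dimnames(covm) <- list(keys, keys)

  frames <- vector("list", n_frames)
  if (scale == 0) {
    for (t in seq_len(n_frames)) frames[[t]] <- coords
  } else {
    set.seed(seed)
    l_mat <- v %*% diag(sqrt(scale / lambda), nrow = length(lambda))
    m <- length(lambda)
    # one displacement field per axis per frame; axes independent (isotropic)
    disp <- array(stats::rnorm(n_frames * m * 3L), dim = c(n_frames, m, 3L))
    for (t in seq_len(n_frames)) {
      delta <- l_mat %*% disp[t, , ]
      frames[[t]] <- coords + delta
    }
  }
  out <- ensemble(topo, frames)
  attr(out, "correlation") <- corr
  attr(out, "covariance") <- covm
  out
}

#' Specification of a planted communication pathway in a dimer
#'
#' Describes the ground truth used by [make_planted_path_dimer()]: a source
#' pocket and a sink pocket in a two-chain system, an ordered residue chain
#' connecting them, the fraction of frames in which the planted contacts are
#' formed, and the density of persistent decoy contacts among the remaining
#' residues.
#'
#' @param n_per_chain residues per chain (chains "A" and "B").
#' @param source_pocket,sink_pocket [residue_selection]s; defaults place the
#'   source at the start of chain A and the sink at the end of chain B,
#'   mimicking an interface pocket and an orthosteric pocket.
#' @param planted_chain character vector of residue keys (`"A:1"` style)
#'   connecting a source residue to a sink residue; consecutive same-chain
#'   entries must not be sequence-adjacent (such pairs are excluded from
#'   structure networks by default).
#' @param persistence fraction of frames in which every planted contact is
#'   formed (the whole pathway toggles together, so the pathway's cross-frame
#'   frequency has this expectation).
#' @param decoy_density persistent decoy contacts per residue among
#'   non-pathway, non-pocket residues.
#' @return list of class `planted_path_spec`.
#' @export
planted_path_spec <- function(n_per_chain = 12L,
                              source_pocket = residue_selection("A", c(1L, 3L),
                                                                label = "PPI_pocket"),
                              sink_pocket = residue_selection("B",
                                                              c(n_per_chain - 2L, n_per_chain),
                                                              label = "orthosteric"),
                              planted_chain = c("A:1", "A:5", "A:8",
                                                "B:4", "B:7", paste0("B:", n_per_chain)),
                              persistence = 1,
                              decoy_density = 0.3) {
  stopifnot(persistence >= 0, persistence <= 1, decoy_density >= 0,
            length(planted_chain) >= 2L)
  if (!planted_chain[1L] %in% selection_keys(source_pocket))
    stop("planted chain must start inside the source pocket")
  if (!planted_chain[length(planted_chain)] %in% selection_keys(sink_pocket))
    stop("planted chain must end inside the sink pocket")
  parts <- strsplit(planted_chain, ":", fixed = TRUE)
  ch <- vapply(parts, `[`, "", 1L)
  rn <- as.integer(vapply(parts, `[`, "", 2L))
  adj <- ch[-1L] == ch[-length(ch)] & abs(diff(rn)) < 2L
  if (any(adj))
    stop("consecutive planted residues are sequence-adjacent: ",
         planted_chain[which(adj)[1L]], " - ", planted_chain[which(adj)[1L] + 1L])
  structure(list(n_per_chain = as.integer(n_per_chain),
                 source_pocket = source_pocket, sink_pocket = sink_pocket,
                 planted_chain = planted_chain, persistence = persistence,
                 decoy_density = decoy_density),
            class = "planted_path_spec")
}

#' Two-chain ensemble with a planted communication pathway
#'
#' Generates a dimer pseudo-structure (C-alpha plus a three-atom side-chain
#' branch per residue) in which consecutive planted-pathway residues have a
#' side-chain atom pair within `contact_cutoff` in exactly the frames where
#' the pathway is "on" (a Bernoulli draw per frame at the spec's
#' persistence), decoy contacts are persistent, and the planted pathway is
#' verified to be the unique minimum-hop source-to-sink route on the union
#' contact graph. Ground truth is attached as attributes.
#'
#' @param spec a [planted_path_spec].
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param contact_cutoff the structure-network distance cutoff the ensemble
#'   is built for (default 4.5 Angstrom).
#' @param max_tries decoy placement retries before giving up.
#' @return an [ensemble] with attributes `planted_path` (residue keys),
#'   `on_frames` (logical per frame), `source_pocket`, `sink_pocket`,
#'   `decoy_edges`.
#' @export
make_planted_path_dimer <- function(spec, n_frames, seed = 1L,
                                    contact_cutoff = 4.5, max_tries = 50L) {
  stopifnot(inherits(spec, "planted_path_spec"), n_frames >= 1L)
  n <- spec$n_per_chain
  keys <- c(paste0("A:", seq_len(n)), paste0("B:", seq_len(n)))
  path <- spec$planted_chain
  if (!all(path %in% keys)) stop("planted chain residue outside the dimer")
  pocket_keys <- unique(c(selection_keys(spec$source_pocket),
                          selection_keys(spec$sink_pocket)))
  free <- setdiff(keys, union(path, pocket_keys))

  path_edges <- cbind(path[-length(path)], path[-1L])
  set.seed(seed)
  # Decoy contacts: random disjoint simple paths among free residues, so a
  # row-wise geometric embedding exists; they can never touch the planted
  # route or the pockets, which keeps the planted pathway's uniqueness
  # checkable rather than assumed.
  n_decoy <- min(round(spec$decoy_density * length(keys)),
                 max(0L, length(free) - 1L))
  decoy_edges <- NULL
  for (try in seq_len(max_tries)) {
    perm <- sample(free)
    de <- if (n_decoy > 0L)
      cbind(perm[seq_len(n_decoy)], perm[seq_len(n_decoy) + 1L])
    g <- igraph::graph_from_edgelist(rbind(path_edges, de), directed = FALSE)
    sp <- igraph::all_shortest_paths(g, from = path[1L],
                                     to = path[length(path)])$vpaths
    ok <- length(sp) == 1L &&
      identical(igraph::as_ids(sp[[1L]]), path)
    if (ok) { decoy_edges <- de; break }
    if (try == max_tries)
      stop("could not place decoy contacts without disturbing the planted ",
           "pathway after ", max_tries, " tries")
  }

  # Geometric embedding: each contact "row" is a straight line of residues
  # 8 A apart; rows are 20 A apart, isolated residues on their own row.
  # Side-chain tips extend 3 A toward a contact partner when the contact is
  # formed and retract to 1 A when it is not, so formed pairs sit ~2 A apart
  # and broken pairs ~6 A apart under an 8 A C-alpha separation.
  pos <- matrix(NA_real_, length(keys), 3L,
                dimnames = list(keys, NULL))
  rows <- list(path)
  if (!is.null(decoy_edges)) {
    # decoy edges form disjoint paths along `perm`; split into runs
    runs <- split(seq_len(nrow(decoy_edges)),
                  cumsum(c(TRUE, decoy_edges[-1L, 1L] != decoy_edges[-nrow(decoy_edges), 2L])))
    for (r in runs)
      rows <- c(rows, list(unique(c(decoy_edges[r, 1L], decoy_edges[r, 2L]))))
  }
  placed <- unlist(rows)
  rows <- c(rows, as.list(setdiff(keys, placed)))
  for (ri in seq_along(rows)) {
    members <- rows[[ri]]
    pos[members, ] <- cbind(8 * (seq_along(members) - 1L),
                            20 * (ri - 1L), 0)
  }

  # partner bookkeeping: tip 1 points at the previous partner, tip 2 at the
  # next; every residue has at most two contact partners by construction
  partners <- stats::setNames(vector("list", length(keys)), keys)
  all_edges <- rbind(path_edges, decoy_edges)
  for (e in seq_len(nrow(all_edges))) {
    a <- all_edges[e, 1L]; b <- all_edges[e, 2L]
    partners[[a]] <- c(partners[[a]], b)
    partners[[b]] <- c(partners[[b]], a)
  }
  if (any(lengths(partners) > 2L)) stop("internal error: residue degree > 2")

  parts <- strsplit(keys, ":", fixed = TRUE)
  topo <- pseudo_topology(
    chain_id = rep(vapply(parts, `[`, "", 1L), each = 4L),
    residue_number = rep(as.integer(vapply(parts, `[`, "", 2L)), each = 4L),
    atom_name = rep(c("CA", "CB", "CG", "CD"), length(keys)),
    element = "C")

  on_frames <- if (spec$persistence >= 1) rep(TRUE, n_frames)
               else if (spec$persistence <= 0) rep(FALSE, n_frames)
               else stats::runif(n_frames) < spec$persistence
  planted_set <- paste(pmin(path_edges[, 1L], path_edges[, 2L]),
                       pmax(path_edges[, 1L], path_edges[, 2L]))

  tip_offset <- function(from, to, extended) {
    u <- to - from
    u <- u / sqrt(sum(u^2))
    if (extended) 3.0 * u else 1.0 * u
  }
  build_frame <- function(on) {
    xyz <- matrix(0, nrow(topo), 3L)
    for (i in seq_along(keys)) {
      k <- keys[i]
      ca <- pos[k, ]
      base <- (i - 1L) * 4L
      xyz[base + 1L, ] <- ca
      xyz[base + 2L, ] <- ca + c(0, 0, 1.5)      # CB, inert branch root
      for (slot in 1:2) {
        row <- base + 2L + slot
        p <- partners[[k]][slot]
        if (is.null(p) || is.na(p)) {
          xyz[row, ] <- ca + c(0, 0, 1.5 + slot)
        } else {
          planted <- paste(min(k, p), max(k, p)) %in% planted_set
          xyz[row, ] <- ca + tip_offset(ca, pos[p, ],
                                        extended = !planted || on)
        }
      }
    }
    xyz
  }
  frame_on <- build_frame(TRUE)
  frame_off <- build_frame(FALSE)
  frames <- lapply(on_frames, function(o) if (o) frame_on else frame_off)

  out <- ensemble(topo, frames)
  attr(out, "planted_path") <- path
  attr(out, "on_frames") <- on_frames
  attr(out, "source_pocket") <- spec$source_pocket
  attr(out, "sink_pocket") <- spec$sink_pocket
  attr(out, "decoy_edges") <- decoy_edges
  out
}

#' Synthetic active/decoy docking score table
#'
#' Decoy scores are standard normal; active scores are shifted by `-d`
#' standard deviations (lower = stronger predicted binding). The closed-form
#' expected AUC for this two-Gaussian model, `pnorm(d / sqrt(2))`, is
#' attached as ground truth.
#'
#' @param n_active,n_decoy class sizes (>= 1).
#' @param d standardized mean separation; `d = 0` is random screening,
#'   negative values give anti-enrichment (allowed, with a message).
#' @param seed integer seed.
#' @return data.frame of class `score_table` with attribute `expected_auc`.
#' @export
make_screening_scores <- function(n_active = 40L, n_decoy = 1440L, d = 0,
                                  seed = 1L) {
  stopifnot(n_active >= 1L, n_decoy >= 1L)
  if (d < 0) message("negative effect size: generating anti-enriched scores")
  set.seed(seed)
  df <- data.frame(
    ligand_id = c(sprintf("act_%05d", seq_len(n_active)),
                  sprintf("dec_%05d", seq_len(n_decoy))),
    score = c(stats::rnorm(n_active, mean = -d), stats::rnorm(n_decoy)),
    label = c(rep("active", n_active), rep("decoy", n_decoy)),
    stringsAsFactors = FALSE)
  attr(df, "expected_auc") <- stats::pnorm(d / sqrt(2))
  class(df) <- c("score_table", "data.frame")
  df
}

#' Synthetic per-frame MM-PBSA component table
#'
#' Independent Gaussian draws per component with the requested means and
#' standard deviations.
#'
#' @param n_frames number of rows.
#' @param means,sds named numeric vectors over (a subset of) `E_vdw`,
#'   `E_ele`, `E_int`, `G_psolv`, `G_npsolv`; unnamed components default to
#'   mean 0 / sd 0. Unknown names are an error.
#' @param seed integer seed.
#' @return data.frame of class `energy_table`.
#' @export
make_energy_table <- function(n_frames, means = c(), sds = c(), seed = 1L) {
  comp <- c("E_vdw", "E_ele", "E_int", "G_psolv", "G_npsolv")
  bad <- setdiff(c(names(means), names(sds)), comp)
  if (length(bad) > 0L)
    stop("unknown energy component(s): ", paste(bad, collapse = ", "))
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  set.seed(seed)
  df <- as.data.frame(lapply(stats::setNames(comp, comp), function(cn) {
    m <- if (cn %in% names(means)) means[[cn]] else 0
    s <- if (cn %in% names(sds)) sds[[cn]] else 0
    if (s == 0) rep(m, n_frames) else stats::rnorm(n_frames, m, s)
  }))
  class(df) <- c("energy_table", "data.frame")
  df
}
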