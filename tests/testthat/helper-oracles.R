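# Independent oracles the implementation is checked against. These share no
# code with the package internals they validate.

# Exhaustive simple-path search with the package's documented tie rules
# (min hops, then max summed interaction, then lexicographically smallest
# residue sequence), implemented by brute-force DFS enumeration.
brute_force_path <- function(i_mat, n_mat, source, sink, i_min,
                             dcc = NULL, corr_min = 0) {
  keys <- rownames(i_mat)
  adj <- i_mat >= i_min & n_mat >= 1L
  if (!is.null(dcc)) adj <- adj & abs(dcc) >= corr_min
  diag(adj) <- FALSE
  paths <- list()
  dfs <- function(node, visited) {
    if (node == sink) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())
    }
    for (nxt in keys[adj[node, ]])
      if (!nxt %in% visited) dfs(nxt, c(visited, nxt))
  }
  dfs(source, source)
  if (length(paths) == 0L) return(NULL)
  hops <- lengths(paths) - 1L
  paths <- paths[hops == min(hops)]
  sums <- vapply(paths, function(p)
    sum(i_mat[cbind(p[-length(p)], p[-1L])]), 0)
  paths <- paths[abs(sums - max(sums)) < 1e-9]
  if (length(paths) == 1L) return(paths[[1L]])
  # lexicographic by (chain, resnum): pad residue numbers for comparison
  pad <- function(p) paste(vapply(strsplit(p, ":", fixed = TRUE), function(g)
    sprintf("%s%08d", g[1L], as.integer(g[2L]) + 10000L), ""), collapse = "|")
  paths[[order(vapply(paths, pad, ""))[1L]]]
}

# Synthesize an interaction-matrix object for graph-level tests without
# going through coordinates.
fake_interactions <- function(i_mat, n_mat = NULL,
                              config = psn_config(i_min = 0)) {
  keys <- rownames(i_mat)
  if (is.null(n_mat)) n_mat <- matrix(as.integer(i_mat > 0),
                                      nrow(i_mat), dimnames = dimnames(i_mat))
  structure(list(I = i_mat, n = n_mat, residues = keys, config = config),
            class = "interaction_matrix")
}

random_interaction_matrix <- function(n_nodes, p_edge = 0.35) {
  keys <- paste0("A:", seq_len(n_nodes))
  i_mat <- matrix(0, n_nodes, n_nodes, dimnames = list(keys, keys))
  up <- which(upper.tri(i_mat))
  on <- up[stats::runif(length(up)) < p_edge]
  i_mat[on] <- round(stats::runif(length(on), 0.5, 10), 3)
  i_mat[lower.tri(i_mat)] <- t(i_mat)[lower.tri(i_mat)]
  i_mat
}

# Mann-Whitney probability of ranking an active above a decoy
# (lower score = better), ties credited one half.
mann_whitney_auc <- function(scores) {
  a <- scores$score[scores$label == "active"]
  d <- scores$score[scores$label == "decoy"]
  cmp <- outer(a, d, FUN = function(x, y) (x < y) + 0.5 * (x == y))
  mean(cmp)
}

# Closed-form accessible areas for two intersecting solvent-expanded
# spheres of radii r1, r2 at centre distance d (spherical caps).
two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(c(4 * pi * r1^2, 4 * pi * r2^2))
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1, 4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# Minimal hand-built ensemble: one frame per coordinate matrix.
toy_ensemble <- function(frames, chain, resnum, atom_name,
                         element = "C", resname = "ALA") {
  n <- length(chain)
  topo <- data.frame(serial = seq_len(n), atom_name = atom_name,
                     element = rep_len(element, n),
                     residue_name = rep_len(resname, n),
                     chain_id = chain, residue_number = resnum,
                     insertion_code = "", occupancy = 1, altloc = "",
                     record = "ATOM", stringsAsFactors = FALSE)
  ensemble(topo, frames)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
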