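test_that("side-chain pair counts match a hand-built geometry", {
  # residues A:1 and A:3, two side-chain atoms each, all 4 cross pairs
  # within 4.5 A -> n = 4, I = 100 * 4 / sqrt(100 * 100) = 4.0
  coords <- rbind(c(0, 0, 0), c(1, 0, 0),   # A:1 CB, CG
                  c(3, 0, 0), c(4, 0, 0))   # A:3 CB, CG
  e <- toy_ensemble(list(coords), chain = rep("A", 4), resnum = c(1, 1, 3, 3),
                    atom_name = rep(c("CB", "CG"), 2))
  im <- interaction_matrix(e, 1, psn_config())
  expect_equal(im$n["A:1", "A:3"], 4L)
  expect_equal(im$I["A:1", "A:3"], 4.0)
  expect_equal(im$I, t(im$I))
  # far residues interact not at all
  far <- coords; far[3:4, 1] <- far[3:4, 1] + 100
  e2 <- toy_ensemble(list(far), chain = rep("A", 4), resnum = c(1, 1, 3, 3),
                     atom_name = rep(c("CB", "CG"), 2))
  expect_equal(interaction_matrix(e2, 1)$I["A:1", "A:3"], 0)
  # default distance cutoff is the conventional 4.5 A
  expect_equal(psn_config()$distance_cutoff, 4.5)
})

test_that("interaction counts agree with a brute-force pair count", {
  set.seed(4)
  n_res <- 6
  coords <- matrix(rnorm(n_res * 3 * 3, sd = 4), ncol = 3)
  e <- toy_ensemble(list(coords), chain = rep("A", n_res * 3),
                    resnum = rep(seq(1, 2 * n_res, by = 2), each = 3),
                    atom_name = rep(c("CB", "CG", "CD"), n_res))
  im <- interaction_matrix(e, 1, psn_config())
  res_of <- rep(seq_len(n_res), each = 3)
  for (i in 1:(n_res - 1)) for (j in (i + 1):n_res) {
    cnt <- 0L
    for (a in which(res_of == i)) for (b in which(res_of == j))
      if (sqrt(sum((coords[a, ] - coords[b, ])^2)) <= 4.5) cnt <- cnt + 1L
    expect_equal(unname(im$n[i, j]), cnt)
  }
})

test_that("sequence-adjacent residues are excluded unless asked for", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0))
  e <- toy_ensemble(list(coords), chain = c("A", "A"), resnum = c(1, 2),
                    atom_name = c("CB", "CB"))
  expect_equal(interaction_matrix(e, 1)$n["A:1", "A:2"], 0L)
  cfg <- psn_config(exclude_bonded = FALSE)
  expect_equal(interaction_matrix(e, 1, cfg)$n["A:1", "A:2"], 1L)
})

test_that("glycine contributes through its C-alpha when configured", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  e <- toy_ensemble(list(coords), chain = c("A", "A"), resnum = c(1, 3),
                    atom_name = c("CA", "CB"), resname = c("GLY", "ALA"))
  expect_equal(interaction_matrix(e, 1)$n["A:1", "A:3"], 1L)
  cfg <- psn_config(gly_calpha = FALSE)
  expect_equal(interaction_matrix(e, 1, cfg)$n["A:1", "A:3"], 0L)
})

test_that("edges form exactly at the interaction cutoff", {
  keys <- paste0("A:", c(1, 3, 5, 7))
  i_mat <- matrix(0, 4, 4, dimnames = list(keys, keys))
  i_mat["A:1", "A:3"] <- i_mat["A:3", "A:1"] <- 3.1
  i_mat["A:3", "A:5"] <- i_mat["A:5", "A:3"] <- 1.2
  i_mat["A:5", "A:7"] <- i_mat["A:7", "A:5"] <- 5.0
  g <- build_psn(fake_interactions(i_mat), psn_config(i_min = 2.0))
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2L)
  expect_setequal(paste(el[, 1], el[, 2]), c("A:1 A:3", "A:5 A:7"))
  # i_min = 0 still requires at least one contacting atom pair
  n_mat <- matrix(0L, 4, 4, dimnames = dimnames(i_mat))
  g0 <- build_psn(fake_interactions(i_mat, n_mat), psn_config(i_min = 0))
  expect_equal(igraph::ecount(g0), 0)
  # transposing the matrix changes nothing
  gt <- build_psn(fake_interactions(t(i_mat)), psn_config(i_min = 2.0))
  expect_true(igraph::identical_graphs(g, gt) ||
                setequal(paste(igraph::as_edgelist(gt)[, 1],
                               igraph::as_edgelist(gt)[, 2]),
                         paste(el[, 1], el[, 2])))
})

test_that("DCC matches direct formula evaluation on constructed motions", {
  # two pseudo-atoms displaced identically -> C = 1; oppositely -> C = -1
  base <- rbind(c(0, 0, 0), c(10, 0, 0))
  frames_same <- lapply(c(-1, 0, 1, 2), function(s)
    base + rbind(c(s, 0, 0), c(s, 0, 0)))
  e_same <- toy_ensemble(frames_same, chain = c("A", "A"), resnum = c(1, 2),
                         atom_name = c("CA", "CA"))
  d <- dcc_matrix(e_same, superpose = FALSE)
  expect_equal(unname(d["A:1", "A:2"]), 1)
  expect_equal(unname(diag(d)), c(1, 1))

  frames_opp <- lapply(c(-1, 0, 1, 2), function(s)
    base + rbind(c(s, 0, 0), c(-s, 0, 0)))
  e_opp <- toy_ensemble(frames_opp, chain = c("A", "A"), resnum = c(1, 2),
                        atom_name = c("CA", "CA"))
  expect_equal(unname(dcc_matrix(e_opp, superpose = FALSE)["A:1", "A:2"]), -1)
})

test_that("DCC flags zero-variance residues and stays within [-1, 1]", {
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  frames <- lapply(1:4, function(s) {
    f <- base; f[1, 2] <- s; f  # only residue 1 moves
  })
  e <- toy_ensemble(frames, chain = rep("A", 3), resnum = 1:3,
                    atom_name = rep("CA", 3))
  d <- dcc_matrix(e, superpose = FALSE)
  expect_setequal(attr(d, "flagged"), c("A:2", "A:3"))
  expect_true(all(d[, "A:2"] == 0))
  expect_true(all(abs(d) <= 1 + 1e-12))
  e_static <- toy_ensemble(rep(list(base), 3), chain = rep("A", 3),
                           resnum = 1:3, atom_name = rep("CA", 3))
  expect_warning(dcc_matrix(e_static, superpose = FALSE), "zero variance")
})

test_that("DCC recovers the analytic GNM correlations", {
  e <- make_gnm_ensemble(25, n_frames = 4000, seed = 19)
  d <- dcc_matrix(e, superpose = FALSE)
  expect_lt(sqrt(mean((unclass(d) - unclass(attr(e, "correlation")))^2)),
            0.05)
})

test_that("DCC with superposition is invariant to whole-frame rotation", {
  e <- make_gnm_ensemble(10, n_frames = 50, seed = 23)
  d0 <- dcc_matrix(e, superpose = TRUE)
  set.seed(3)
  spun <- lapply(e$frames, function(f) f %*% t(random_rotation()))
  d1 <- dcc_matrix(ensemble(e$topology, spun), superpose = TRUE)
  # two-pass mean-fit superposition compensates per-frame rotations up to
  # its own convergence tolerance
  expect_lt(max(abs(unclass(d1) - unclass(d0))), 5e-3)
})

test_that("path search matches exhaustive enumeration with the tie rules", {
  # spec toy: a 6-node graph, then systematic random graphs
  set.seed(101)
  for (trial in 1:40) {
    n <- sample(4:10, 1)
    i_mat <- random_interaction_matrix(n)
    im <- fake_interactions(i_mat)
    g <- build_psn(im, psn_config(i_min = 0))
    src <- "A:1"; snk <- paste0("A:", n)
    got <- shortest_path(g, src, snk, corr_min = 0)
    want <- brute_force_path(i_mat, im$n, src, snk, i_min = 0)
    if (is.null(want)) expect_null(got)
    else expect_equal(got$path, want)
  }
})

test_that("the correlation filter reroutes exactly as the oracle predicts", {
  keys <- paste0("A:", 1:6)
  i_mat <- matrix(0, 6, 6, dimnames = list(keys, keys))
  edge <- function(a, b, w) i_mat[a, b] <<- i_mat[b, a] <<- w
  edge("A:1", "A:2", 5); edge("A:2", "A:6", 5)          # 2-hop route
  edge("A:1", "A:3", 4); edge("A:3", "A:4", 4)
  edge("A:4", "A:5", 4); edge("A:5", "A:6", 4)          # 4-hop detour
  dcc <- matrix(1, 6, 6, dimnames = list(keys, keys))
  dcc["A:2", "A:6"] <- dcc["A:6", "A:2"] <- 0.1         # weakly correlated bridge
  im <- fake_interactions(i_mat)
  g <- build_psn(im, psn_config(i_min = 0))
  free <- shortest_path(g, "A:1", "A:6", dcc = dcc, corr_min = 0)
  expect_equal(free$path, c("A:1", "A:2", "A:6"))
  filt <- shortest_path(g, "A:1", "A:6", dcc = dcc, corr_min = 0.3)
  want <- brute_force_path(i_mat, im$n, "A:1", "A:6", i_min = 0,
                           dcc = dcc, corr_min = 0.3)
  expect_equal(filt$path, want)
  expect_equal(filt$hops, 4L)
  # source = sink is a zero-hop path, not an error
  self <- shortest_path(g, "A:3", "A:3")
  expect_equal(self$hops, 0L)
  expect_error(shortest_path(g, "A:1", "B:9"), "not in graph")
})

test_that("raising thresholds never adds edges or pathways", {
  set.seed(7)
  i_mat <- random_interaction_matrix(9, p_edge = 0.5)
  im <- fake_interactions(i_mat)
  e_prev <- Inf
  for (im_min in c(0, 2, 4, 6, 8)) {
    ec <- igraph::ecount(build_psn(im, psn_config(i_min = im_min)))
    expect_lte(ec, e_prev)
    e_prev <- ec
  }
  d <- make_planted_path_dimer(planted_path_spec(persistence = 0.6),
                               n_frames = 40, seed = 2)
  graphs <- psn_per_frame(d, psn_config(i_min = 0))
  src <- attr(d, "source_pocket"); snk <- attr(d, "sink_pocket")
  n_prev <- Inf
  for (fm in c(0.1, 0.5, 0.9)) {
    t <- tally_paths(graphs, src, snk, freq_min = fm)
    expect_lte(attr(t, "n_above"), n_prev)
    n_prev <- attr(t, "n_above")
  }
})

test_that("pathway frequency equals the planted on-fraction exactly", {
  spec <- planted_path_spec(persistence = 0.5)
  d <- make_planted_path_dimer(spec, n_frames = 200, seed = 12)
  tally <- tally_paths(psn_per_frame(d, psn_config(i_min = 0)),
                       attr(d, "source_pocket"), attr(d, "sink_pocket"))
  expect_equal(tally$frequency[1], mean(attr(d, "on_frames")))
  expect_error(tally_paths(list(), attr(d, "source_pocket"),
                           attr(d, "sink_pocket")), "at least one")
  expect_error(tally_paths(psn_per_frame(d)[1], character(0), "B:1"),
               "empty pocket")
})
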