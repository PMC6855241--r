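# Conformational clustering: superposition, pairwise RMSD, k-means on a
# classical-MDS embedding, medoid representatives.

#' Least-squares (Kabsch) superposition
#'
#' Fits `mobile` onto `reference` by the optimal proper rotation and
#' translation computed on the selected atoms, applies the transform to all
#' mobile atoms, and reports the post-fit RMSD over the selection. The
#' rotation determinant is forced to +1, so reflections are never applied.
#'
#' @param mobile,reference `n x 3` coordinate matrices with identical atom
#'   ordering.
#' @param atom_sel integer atom indices to fit on (default: all atoms).
#' @return list with `coords` (transformed mobile, all atoms), `rmsd`
#'   (Angstrom, post-fit over the selection), `rotation`, `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, atom_sel = NULL) {
  if (is.null(atom_sel)) atom_sel <- seq_len(nrow(reference))
  if (length(atom_sel) < 3L)
    stop("superposition needs at least 3 selected atoms")
  p <- mobile[atom_sel, , drop = FALSE]
  q <- reference[atom_sel, , drop = FALSE]
  if (nrow(p) != nrow(q)) stop("selections differ in length")
  cp <- colMeans(p); cq <- colMeans(q)
  p0 <- sweep(p, 2L, cp); q0 <- sweep(q, 2L, cq)
  sv_ref <- svd(q0)$d
  if (sv_ref[2L] < 1e-8 * max(sv_ref[1L], 1))
    stop("degenerate fit: selected reference atoms are collinear")
  s <- svd(crossprod(p0, q0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(mobile, 2L, cp) %*% t(rot)
  moved <- sweep(moved, 2L, cq, `+`)
  dev <- moved[atom_sel, , drop = FALSE] - reference[atom_sel, , drop = FALSE]
  list(coords = moved,
       rmsd = sqrt(mean(rowSums(dev^2))),
       rotation = rot,
       translation = cq - as.vector(rot %*% cp))
}

#' Pairwise best-fit RMSD matrix over an ensemble
#'
#' Each entry is the post-superposition RMSD between a frame pair over the
#' stated atom selection (e.g. interface backbone atoms); computed once per
#' pair, so the matrix is symmetric by construction with a zero diagonal.
#'
#' @param ens an [ensemble] with >= 2 frames.
#' @param atom_sel integer atom indices (default all atoms).
#' @return `n_frames x n_frames` numeric matrix of class `rmsd_matrix`
#'   (Angstrom).
#' @export
pairwise_rmsd <- function(ens, atom_sel = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  nf <- n_frames(ens)
  if (nf < 2L) stop("pairwise RMSD needs at least 2 frames")
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    fi <- get_frame(ens, i)
    for (j in seq(i + 1L, nf)) {
      r <- kabsch_superpose(get_frame(ens, j), fi, atom_sel)$rmsd
      m[i, j] <- m[j, i] <- r
    }
  }
  class(m) <- c("rmsd_matrix", class(m))
  m
}

#' k-means clustering of frames from an RMSD matrix
#'
#' The RMSD matrix is embedded into a Euclidean space by classical
#' multidimensional scaling (up to `min(n_frames - 1, 10)` dimensions) and
#' k-means is run on the embedding, keeping the best of `n_init` seeded
#' restarts by within-cluster sum of squares. Each cluster is represented by
#' its medoid: the member frame minimising summed RMSD to the rest of the
#' cluster (ties go to the lowest frame index). A flag switches the
#' representative to the centroid-nearest frame in embedding space.
#'
#' @param rmsd an `rmsd_matrix` (or any symmetric distance matrix in
#'   Angstrom).
#' @param k number of clusters, `1 <= k <= n_frames`.
#' @param seed integer seed for the restarts.
#' @param n_init number of k-means restarts.
#' @param representative `"medoid"` (default) or `"centroid"`.
#' @return object of class `frame_clustering`: list with `labels`, `k`,
#'   `populations`, `medoids`, `tot_withinss`, `seed`, `n_init`.
#' @export
kmeans_frames <- function(rmsd, k, seed = 1L, n_init = 10L,
                          representative = c("medoid", "centroid")) {
  representative <- match.arg(representative)
  n <- nrow(rmsd)
  if (k < 1L || k > n) stop("k must be between 1 and the number of frames")
  ndim <- max(1L, min(n - 1L, 10L))
  emb <- suppressWarnings(stats::cmdscale(rmsd, k = ndim))
  if (is.null(dim(emb)) || ncol(emb) == 0L)
    emb <- matrix(0, n, 1L)
  if (k == 1L) {
    labels <- rep(1L, n)
    tot_wss <- sum(scale(emb, scale = FALSE)^2)
  } else {
    set.seed(seed)
    km <- NULL
    for (attempt in seq_len(n_init)) {
      fit <- try(stats::kmeans(emb, centers = k, nstart = 1L,
                               iter.max = 100L), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(km) || fit$tot.withinss < km$tot.withinss) km <- fit
    }
    if (is.null(km))
      stop("k-means failed in all ", n_init, " restarts (k too large for ",
           "the number of distinct frames?)")
    labels <- as.integer(km$cluster)
    tot_wss <- km$tot.withinss
  }
  medoids <- integer(k)
  for (c in seq_len(k)) {
    members <- which(labels == c)
    if (representative == "medoid") {
      tot <- rowSums(rmsd[members, members, drop = FALSE])
    } else {
      ctr <- colMeans(emb[members, , drop = FALSE])
      tot <- rowSums(sweep(emb[members, , drop = FALSE], 2L, ctr)^2)
    }
    medoids[c] <- members[which.min(tot)]  # which.min takes the lowest index on ties
  }
  structure(list(labels = labels, k = as.integer(k),
                 populations = as.vector(table(factor(labels, levels = seq_len(k)))) / n,
                 medoids = medoids, tot_withinss = tot_wss,
                 seed = seed, n_init = n_init,
                 representative = representative),
            class = "frame_clustering")
}

#' @export
print.frame_clustering <- function(x, ...) {
  cat("k-means frame clustering: k =", x$k, "\n")
  cat("populations:", paste(sprintf("%.3f", x$populations), collapse = " "),
      "\n")
  cat("representative frames:", paste(x$medoids, collapse = " "), "\n")
  invisible(x)
}

#' Extract representative frames as a sub-ensemble
#'
#' @param ens the clustered [ensemble].
#' @param clustering a [kmeans_frames()] result.
#' @return an [ensemble] of the k representative frames, in cluster order.
#' @export
representative_frames <- function(ens, clustering) {
  stopifnot(inherits(ens, "ensemble"), inherits(clustering, "frame_clustering"))
  ensemble(ens$topology, ens$frames[clustering$medoids])
}
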