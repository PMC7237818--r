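# Diffusion pseudotime on an embedding.
#
# Construction: k-nearest-neighbour graph on the embedding (Euclidean),
# Gaussian kernel with per-cell local scaling (sigma_i = distance to the
# ceiling(k/2)-th neighbour), symmetrized by union, anisotropically normalized
# (alpha = 1, which removes the influence of sampling density), then
# pseudotime = Euclidean distance from the root cell in the space of the top
# diffusion components, each weighted by eigenvalue/(1 - eigenvalue). A
# user-supplied pseudotime vector can replace this routine anywhere the
# package consumes one.

#' Diffusion pseudotime
#'
#' @param embedding Cells x dimensions numeric matrix with cell ids as
#'   rownames (principal components or topic contributions).
#' @param root_cell Id of the root cell (pseudotime 0).
#' @param k_neighbors Number of nearest neighbours for the kernel graph
#'   (must be smaller than the number of cells).
#' @param n_components Number of diffusion components used for the distance.
#' @return Named numeric vector of pseudotimes (>= 0, root = 0), in the input
#'   cell order. Values are invariant to permuting the input rows.
#' @export
diffusion_pseudotime <- function(embedding, root_cell, k_neighbors = 15,
                                 n_components = 10) {
  if (is.null(rownames(embedding))) stopf("embedding must have cell ids as rownames")
  input_order <- rownames(embedding)
  embedding <- embedding[order(rownames(embedding)), , drop = FALSE]
  n <- nrow(embedding)
  if (!root_cell %in% rownames(embedding)) stopf("root cell '%s' not in embedding", root_cell)
  if (k_neighbors >= n) stopf("k_neighbors (%d) must be < number of cells (%d)",
                              k_neighbors, n)
  n_components <- min(n_components, n - 1L)

  d <- as.matrix(stats::dist(embedding))
  # kNN mask and local kernel scales
  sigma <- numeric(n)
  knn <- matrix(FALSE, n, n)
  k_half <- ceiling(k_neighbors / 2)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    ord <- ord[ord != i][seq_len(k_neighbors)]
    knn[i, ord] <- TRUE
    sigma[i] <- d[i, ord[k_half]]
  }
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-12)
  mask <- knn | t(knn)

  comps <- graph_components(mask)
  if (max(comps) > 1L) {
    sizes <- tabulate(comps)
    stopf("k-NN graph is disconnected: %d components of sizes %s",
          max(comps), paste(sizes, collapse = ", "))
  }

  w <- exp(-d^2 / outer(sigma, sigma))
  w[!mask] <- 0
  diag(w) <- 0
  # anisotropic normalization (alpha = 1)
  q <- rowSums(w)
  k_mat <- w / outer(q, q)
  d2 <- rowSums(k_mat)
  a_sym <- k_mat / sqrt(outer(d2, d2))
  eig <- eigen(a_sym, symmetric = TRUE)
  lambda <- eig$values[seq(2, n_components + 1)]
  psi <- eig$vectors[, seq(2, n_components + 1), drop = FALSE] / sqrt(d2)
  lambda <- pmin(pmax(lambda, 0), 1 - 1e-10)
  wts <- lambda / (1 - lambda)
  scaled <- sweep(psi, 2, wts, `*`)
  root <- scaled[match(root_cell, rownames(embedding)), ]
  pt <- sqrt(rowSums(sweep(scaled, 2, root, `-`)^2))
  names(pt) <- rownames(embedding)
  pt[input_order]
}

# Connected components of an undirected adjacency mask (logical matrix).
graph_components <- function(mask) {
  n <- nrow(mask)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(mask[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
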