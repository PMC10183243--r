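# Independent oracles used to cross-check the package's own algorithms.
# These deliberately use different algorithms from the implementation.

# ADMM solver for the penalized Gaussian likelihood problem
#   min_Theta  -log det Theta + tr(S Theta) + lambda ||Theta||_1,offdiag
# (scaled-form ADMM with eigendecomposition Theta-update).
admm_glasso <- function(S, lambda, rho = 1, max_iter = 5000, tol = 1e-8) {
  p <- ncol(S)
  Theta <- diag(p); Z <- diag(p); U <- matrix(0, p, p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (it in seq_len(max_iter)) {
    e <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    th <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    Theta <- e$vectors %*% (th * t(e$vectors))
    Z_old <- Z
    A <- Theta + U
    Z <- soft(A, lambda / rho)
    diag(Z) <- diag(A)           # unpenalized diagonal
    U <- U + Theta - Z
    if (max(abs(Theta - Z)) < tol && max(abs(Z - Z_old)) < tol) break
  }
  Z
}

# Exhaustive enumeration of all simple paths between two nodes; returns the
# fractional shortest-path credit for every intermediate node.
enumerate_betweenness <- function(W, comm) {
  p <- ncol(W)
  A <- abs(W)
  dist_edge <- ifelse(A > 0, 1 / A, Inf)
  credit <- numeric(p)
  all_paths <- function(a, c) {
    paths <- list()
    walk <- function(node, visited, len) {
      if (node == c) {
        paths[[length(paths) + 1]] <<- list(path = visited, len = len)
        return()
      }
      for (nb in seq_len(p)) {
        if (is.finite(dist_edge[node, nb]) && !(nb %in% visited)) {
          walk(nb, c(visited, nb), len + dist_edge[node, nb])
        }
      }
    }
    walk(a, a, 0)
    paths
  }
  for (a in seq_len(p - 1)) {
    for (c in (a + 1):p) {
      if (comm[a] == comm[c]) next
      paths <- all_paths(a, c)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      shortest <- which(lens <= min(lens) + 1e-9)
      for (s in shortest) {
        inner <- setdiff(paths[[s]]$path, c(a, c))
        credit[inner] <- credit[inner] + 1 / length(shortest)
      }
    }
  }
  credit
}

# random symmetric weight matrix with zero diagonal
random_weight_matrix <- function(p, density = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < density]
  W[on] <- runif(length(on), 0.05, 0.6) * sample(c(-1, 1), length(on), TRUE)
  W <- W + t(W)
  dimnames(W) <- list(paste0("item", 1:p), paste0("item", 1:p))
  W
}

# random partition of p nodes into k non-empty communities
random_partition <- function(p, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    comm <- sample(paste0("C", 1:k), p, replace = TRUE)
    if (length(unique(comm)) == k) break
  }
  ids <- paste0("item", 1:p)
  community_map(split(ids, comm))
}

# write a small response CSV for ingestion tests
write_response_csv <- function(values, path, item_ids = NULL) {
  df <- as.data.frame(values)
  if (!is.null(item_ids)) colnames(df) <- item_ids
  write.csv(df, path, row.names = FALSE)
  path
}
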