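#' Partial correlations from a precision matrix
#'
#' Converts a symmetric positive-definite precision matrix `K` to the
#' edge-weight matrix of the Gaussian graphical model:
#' `w_ij = -K_ij / sqrt(K_ii K_jj)` off the diagonal, 0 on it. The weight
#' of an edge is the correlation between two variables after conditioning
#' on all others.
#'
#' @param K symmetric precision matrix with positive diagonal.
#' @return Symmetric weight matrix with zero diagonal and entries in
#'   (-1, 1).
#' @export
partial_correlations <- function(K) {
  K <- as.matrix(K)
  if (any(diag(K) <= 0)) stop("precision diagonal must be positive",
                              call. = FALSE)
  d <- 1 / sqrt(diag(K))
  W <- -K * tcrossprod(d)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(K)
  W
}

# repair a borderline non-PSD correlation matrix by eigenvalue clipping
repair_psd <- function(r, eps = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(r = r, repaired = FALSE))
  v <- pmax(e$values, eps)
  r2 <- e$vectors %*% (v * t(e$vectors))
  d <- 1 / sqrt(diag(r2))
  r2 <- r2 * tcrossprod(d)
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- dimnames(r)
  list(r = r2, repaired = TRUE)
}

#' Graphical LASSO along a penalty path
#'
#' For each penalty `lambda` (descending), solves the L1-penalized
#' Gaussian log-likelihood problem
#' `max_K log det K - tr(RK) - lambda ||K||_1,off` (off-diagonal penalty
#' only, the convention of EBIC-glasso network estimation) by block
#' coordinate descent with warm starts along the path.
#'
#' @param r a `cor_matrix` or plain correlation matrix.
#' @param lambdas non-negative penalties, sorted descending internally.
#' @param tol convergence tolerance (relative to the mean absolute
#'   off-diagonal correlation).
#' @param max_iter maximum outer sweeps per penalty.
#' @return A list of `precision_estimate` objects, each with elements `K`
#'   (precision), `lambda`, `n_edges` (nonzero upper-triangle
#'   off-diagonals) and `loglik_q` (the profile term
#'   `log det K - tr(RK)`).
#' @export
glasso_path <- function(r, lambdas, tol = 1e-4, max_iter = 200) {
  R <- if (inherits(r, "cor_matrix")) r$r else as.matrix(r)
  if (any(lambdas < 0)) stop("penalties must be non-negative", call. = FALSE)
  rep <- repair_psd(R)
  if (rep$repaired) {
    message("correlation matrix not positive semi-definite; ",
            "repaired by eigenvalue clipping")
    R <- rep$r
  }
  lambdas <- sort(lambdas, decreasing = TRUE)
  W <- NULL; B <- NULL
  out <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fit <- .glasso_cd(R, lambdas[i], W_init = W, B_init = B,
                      tol = tol, max_iter = max_iter)
    if (!fit$converged) {
      stop(sprintf("graphical lasso did not converge at lambda = %.6g",
                   lambdas[i]), call. = FALSE)
    }
    W <- fit$W; B <- fit$B
    K <- fit$K
    dimnames(K) <- dimnames(R)
    ut <- K[upper.tri(K)]
    out[[i]] <- structure(
      list(K = K, lambda = lambdas[i], n_edges = sum(ut != 0),
           loglik_q = as.numeric(determinant(K, logarithm = TRUE)$modulus) -
             sum(R * K)),
      class = "precision_estimate"
    )
  }
  out
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' `EBIC = -2 l + E log n + 4 E gamma log p` where
#' `l = (n/2)(log det K - tr(RK))` is the Gaussian profile log-likelihood
#' (additive constants dropped) and `E` is the number of edges (nonzero
#' upper-triangle off-diagonals). `gamma = 0` recovers the ordinary BIC;
#' larger `gamma` favors sparser models.
#'
#' @param est a `precision_estimate` from [glasso_path()].
#' @param r the `cor_matrix` (or matrix) the model was fitted to.
#' @param n sample size.
#' @param gamma EBIC hyperparameter, `>= 0`.
#' @return The EBIC value (numeric scalar).
#' @export
ebic_score <- function(est, r, n, gamma = 0.5) {
  R <- if (inherits(r, "cor_matrix")) r$r else as.matrix(r)
  K <- if (inherits(est, "precision_estimate")) est$K else as.matrix(est)
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) stop("precision matrix is not positive definite",
                         call. = FALSE)
  p <- ncol(K)
  E <- sum(K[upper.tri(K)] != 0)
  ll <- (n / 2) * (as.numeric(ld$modulus) - sum(R * K))
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate the EBIC-selected partial-correlation network
#'
#' Fits the graphical LASSO over a log-spaced penalty path (by default 100
#' values from `lambda_max = max |r_ij|` down to `0.01 lambda_max`) and
#' returns the model minimizing the EBIC with hyperparameter `gamma`
#' (default 0.50, the conventional choice for symptom networks; ties are
#' broken toward the sparser model). Edge weights are partial
#' correlations.
#'
#' @param r a `cor_matrix` from [correlation_matrix()], or a correlation
#'   matrix with a sample size passed via `n`.
#' @param n sample size (taken from `r` when it is a `cor_matrix`).
#' @param gamma EBIC hyperparameter.
#' @param n_lambda number of penalties on the path.
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @return An object of class `ggm_network`: list with `W` (partial
#'   correlation weights), `item_ids`, `lambda` (selected penalty), `ebic`,
#'   `gamma`, `n_edges`, `n`, and the full `path` diagnostics
#'   (`lambda`, `ebic`, `n_edges` per model).
#' @export
select_network <- function(r, n = NULL, gamma = 0.5, n_lambda = 100,
                           lambda_min_ratio = 0.01) {
  if (inherits(r, "cor_matrix")) {
    if (is.null(n)) n <- r$n
    R <- r$r
  } else {
    R <- as.matrix(r)
    if (is.null(n)) stop("sample size `n` required", call. = FALSE)
  }
  item_ids <- colnames(R)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(R)))
  dimnames(R) <- list(item_ids, item_ids)

  lambda_max <- max(abs(R[upper.tri(R)]))
  if (lambda_max == 0) lambda_max <- 1e-3  # fully diagonal input
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  path <- glasso_path(R, lambdas)
  ebics <- vapply(path, ebic_score, numeric(1), r = R, n = n, gamma = gamma)
  edges <- vapply(path, function(e) e$n_edges, numeric(1))
  # minimal EBIC; on (near-)ties prefer the sparser model
  best <- which(ebics <= min(ebics) + 1e-9)
  best <- best[which.min(edges[best])]
  est <- path[[best]]
  W <- partial_correlations(est$K)
  structure(
    list(W = W, item_ids = item_ids, lambda = est$lambda,
         ebic = ebics[best], gamma = gamma, n_edges = est$n_edges, n = n,
         path = data.frame(lambda = vapply(path, `[[`, numeric(1), "lambda"),
                           n_edges = edges, ebic = ebics)),
    class = "ggm_network"
  )
}

#' @export
print.ggm_network <- function(x, ...) {
  p <- length(x$item_ids)
  cat(sprintf(
    "<ggm_network> %d nodes, %d/%d edges (lambda = %.4g, gamma = %.2f, n = %d)\n",
    p, x$n_edges, p * (p - 1) / 2, x$lambda, x$gamma, x$n
  ))
  invisible(x)
}

#' Network edges in long format
#'
#' @param net a `ggm_network` (or bare weight matrix).
#' @param keep_zero include absent edges as zero-weight rows.
#' @return Data frame `item_a, item_b, weight`, upper triangle only.
#' @export
edge_list <- function(net, keep_zero = FALSE) {
  W <- if (inherits(net, "ggm_network")) net$W else as.matrix(net)
  ids <- colnames(W)
  if (is.null(ids)) ids <- paste0("item", seq_len(ncol(W)))
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(
    item_a = ids[idx[, 1]], item_b = ids[idx[, 2]],
    weight = W[idx], stringsAsFactors = FALSE
  )
  if (!keep_zero) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network as GraphML
#'
#' Nodes carry their community as an attribute; edge weights are the
#' partial correlations.
#'
#' @param net a `ggm_network`.
#' @param cm a [community_map()] covering the network's items.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, cm, path) {
  stopifnot(inherits(net, "ggm_network"))
  validate_communities(cm, net$item_ids)
  g <- igraph::graph_from_adjacency_matrix(
    abs(net$W), mode = "undirected", weighted = TRUE, diag = FALSE
  )
  igraph::V(g)$community <- unname(cm$assignment[net$item_ids])
  # keep signed weights as an explicit attribute
  el <- igraph::as_edgelist(g, names = TRUE)
  igraph::E(g)$partial_correlation <-
    net$W[cbind(match(el[, 1], net$item_ids), match(el[, 2], net$item_ids))]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
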