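#' Build a synthetic symptom-network ground truth
#'
#' Constructs a sparse, block-structured partial-correlation matrix
#' emulating the topology of mental-distress symptom networks: dense
#' positive edges within each community (subscale), a few weaker
#' cross-community "bridge" edges, and a latent-Gaussian threshold model
#' for the ordinal responses. Within-community edges are placed on a
#' random pattern with the given density; each pair of communities gets
#' `bridges_per_pair` bridge edges between randomly chosen node pairs. The
#' target partial correlations are mapped to a precision matrix, which is
#' inflated on the diagonal until safely positive definite, and the
#' realized partial correlations are re-derived so the recorded truth is
#' always self-consistent (`partial_correlations(K)` reproduces `W`
#' exactly). The implied covariance is rescaled to unit diagonal.
#'
#' @param communities a [community_map()] or an integer vector of
#'   community sizes (default `c(7, 7, 7)`, the DASS-21 layout).
#' @param within_pc target partial correlation of within-community edges.
#' @param within_density share of within-community pairs that get an edge.
#' @param bridges_per_pair cross-community edges per community pair.
#' @param bridge_pc target partial correlation of bridge edges.
#' @param thresholds 3 increasing latent cut-points shared by all items;
#'   the default `(0.3, 1.0, 1.8)` yields the right-skewed endorsement
#'   typical of symptom scales.
#' @param seed RNG seed; the same seed reproduces the model exactly.
#' @return An object of class `synthetic_model`: list with `K` (true
#'   precision), `W` (true partial correlations), `Sigma` (unit-diagonal
#'   covariance), `communities`, `item_ids`, `thresholds` and `seed`.
#' @export
make_truth <- function(communities = c(7, 7, 7), within_pc = 0.25,
                       within_density = 0.5, bridges_per_pair = 2,
                       bridge_pc = 0.15, thresholds = c(0.3, 1.0, 1.8),
                       seed = 1) {
  if (inherits(communities, "community_map")) {
    cm <- communities
    item_ids <- names(cm$assignment)
  } else {
    sizes <- as.integer(communities)
    p <- sum(sizes)
    item_ids <- paste0("item", seq_len(p))
    labs <- if (length(sizes) == 3) {
      c("Stress", "Anxiety", "Depression")
    } else {
      paste0("C", seq_along(sizes))
    }
    cm <- community_map(stats::setNames(
      split(item_ids, rep(seq_along(sizes), sizes)), labs))
  }
  p <- length(item_ids)
  if (abs(within_pc) >= 1 || abs(within_pc) <= 0 ||
      abs(bridge_pc) >= 1 || abs(bridge_pc) <= 0) {
    stop("edge partial correlations must lie in (0, 1) in magnitude",
         call. = FALSE)
  }
  if (!all(diff(thresholds) > 0) || length(thresholds) != 3) {
    stop("thresholds must be 3 strictly increasing cut-points",
         call. = FALSE)
  }
  comm <- cm$assignment[item_ids]
  set.seed(seed)

  Wt <- matrix(0, p, p, dimnames = list(item_ids, item_ids))
  for (lab in cm$communities) {
    members <- which(comm == lab)
    prs <- utils::combn(members, 2)
    take <- which(stats::runif(ncol(prs)) < within_density)
    if (length(take) == 0) take <- sample(ncol(prs), 1)
    for (k in take) {
      Wt[prs[1, k], prs[2, k]] <- within_pc
      Wt[prs[2, k], prs[1, k]] <- within_pc
    }
  }
  labs <- cm$communities
  if (length(labs) > 1 && bridges_per_pair > 0) {
    for (a in seq_len(length(labs) - 1)) {
      for (b in (a + 1):length(labs)) {
        ma <- which(comm == labs[a]); mb <- which(comm == labs[b])
        cand <- expand.grid(i = ma, j = mb)
        pick <- cand[sample(nrow(cand), min(bridges_per_pair, nrow(cand))), ]
        for (k in seq_len(nrow(pick))) {
          Wt[pick$i[k], pick$j[k]] <- bridge_pc
          Wt[pick$j[k], pick$i[k]] <- bridge_pc
        }
      }
    }
  }

  # target precision with unit diagonal: K_ij = -w_ij; inflate the diagonal
  # until comfortably SPD (diagonal-dominance repair)
  K <- -Wt
  diag(K) <- 1
  for (tries in 0:50) {
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 0.05) break
    diag(K) <- diag(K) + (0.06 - ev)
  }
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("cannot reach a positive-definite precision for these magnitudes",
         call. = FALSE)
  }
  Sigma0 <- solve(K)
  s <- sqrt(diag(Sigma0))
  # Sigma = D Sigma0 D with D = diag(1/s) has unit diagonal, and the
  # matching precision is diag(s) K diag(s): zero-pattern preserved exactly,
  # partial correlations unchanged
  Sigma <- Sigma0 * tcrossprod(1 / s)
  Sigma <- (Sigma + t(Sigma)) / 2
  diag(Sigma) <- 1
  K <- K * tcrossprod(s)
  K <- (K + t(K)) / 2
  K[Wt == 0 & row(K) != col(K)] <- 0
  W <- partial_correlations(K)
  dimnames(K) <- dimnames(Sigma) <- list(item_ids, item_ids)

  structure(
    list(K = K, W = W, Sigma = Sigma, communities = cm,
         item_ids = item_ids,
         thresholds = matrix(thresholds, p, 3, byrow = TRUE,
                             dimnames = list(item_ids, NULL)),
         seed = seed),
    class = "synthetic_model"
  )
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat(sprintf("<synthetic_model> %d items, %d true edges, %d communities\n",
              length(x$item_ids), sum(x$W[upper.tri(x$W)] != 0),
              length(x$communities$communities)))
  invisible(x)
}

#' Sample ordinal questionnaire responses from a synthetic model
#'
#' Draws latent multivariate-normal vectors from the model's
#' unit-diagonal covariance and discretizes each item at its thresholds
#' into the four response categories 0--3.
#'
#' @param model a `synthetic_model` from [make_truth()].
#' @param n respondents to draw (>= 10).
#' @param seed RNG seed.
#' @return An [item_response_matrix()].
#' @export
sample_ordinal <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "synthetic_model"))
  if (n < 10) stop("need n >= 10", call. = FALSE)
  p <- length(model$item_ids)
  Z <- sample_latent(model, n, seed)
  X <- matrix(0L, n, p, dimnames = list(NULL, model$item_ids))
  for (j in seq_len(p)) {
    X[, j] <- as.integer(findInterval(Z[, j], model$thresholds[j, ]))
  }
  item_response_matrix(X, model$item_ids)
}

#' Sample the latent (continuous) layer of a synthetic model
#'
#' Draws the multivariate-normal vectors underlying [sample_ordinal()]
#' without discretizing them. Useful for validating estimators against
#' the model's closed-form quantities free of ordinal coarsening.
#'
#' @inheritParams sample_ordinal
#' @return Numeric n x p matrix with items as columns.
#' @export
sample_latent <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "synthetic_model"))
  p <- length(model$item_ids)
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p) %*% chol(model$Sigma)
  colnames(Z) <- model$item_ids
  Z
}

#' Edge-recovery metrics against a known truth
#'
#' Compares an estimated network's sparsity pattern and strength ordering
#' with the generating model: sensitivity (share of true edges
#' recovered), specificity (share of truly absent edges kept absent), and
#' the Spearman correlation between true and estimated node strengths.
#'
#' @param truth a `synthetic_model`.
#' @param est a `ggm_network` (or weight matrix) over the same items.
#' @return List with `sensitivity`, `specificity` and `strength_rank_cor`.
#' @export
recovery_metrics <- function(truth, est) {
  stopifnot(inherits(truth, "synthetic_model"))
  West <- if (inherits(est, "ggm_network")) est$W else as.matrix(est)
  if (!all(dim(West) == dim(truth$W))) {
    stop("dimension mismatch between truth and estimate", call. = FALSE)
  }
  ut <- upper.tri(truth$W)
  true_edge <- truth$W[ut] != 0
  est_edge <- West[ut] != 0
  sens <- if (any(true_edge)) mean(est_edge[true_edge]) else NA_real_
  spec <- if (any(!true_edge)) mean(!est_edge[!true_edge]) else NA_real_
  list(
    sensitivity = sens,
    specificity = spec,
    strength_rank_cor = suppressWarnings(
      cor(node_strength(truth$W), node_strength(West), method = "spearman"))
  )
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Emits a response CSV in the ingestion dialect plus a JSON description
#' of the generating model (edges, thresholds, seed).
#'
#' @param model a `synthetic_model`.
#' @param x an [item_response_matrix()] sampled from it.
#' @param dir output directory (created if needed).
#' @return Named list of the two file paths, invisibly.
#' @export
write_synthetic <- function(model, x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "responses.csv")
  truth_path <- file.path(dir, "truth.json")
  write_responses(x, data_path)
  edges <- edge_list(model$W)
  jsonlite::write_json(
    list(item_ids = model$item_ids,
         communities = split(names(model$communities$assignment),
                             model$communities$assignment),
         edges = edges,
         thresholds = model$thresholds[1, ],
         seed = model$seed),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(list(responses = data_path, truth = truth_path))
}
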