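# deterministic per-(proportion, replicate) seed, independent of execution
# order; kept below 2^31 - 1
cell_seed <- function(master, cell) {
  (as.numeric(master) * 48271 + 104729 * cell) %% 2147483647
}

# node-index procedures re-run on each subsample; each returns a per-node
# numeric vector from raw ordinal responses
index_procedures <- function(cm, gamma, gamma_pred, n_lambda,
                             lambda_min_ratio) {
  list(
    strength = function(x) {
      r <- correlation_matrix(npn_transform(x))
      node_strength(select_network(r, gamma = gamma, n_lambda = n_lambda,
                                   lambda_min_ratio = lambda_min_ratio))
    },
    bridge_strength = function(x) {
      r <- correlation_matrix(npn_transform(x))
      bridge_strength(select_network(r, gamma = gamma, n_lambda = n_lambda,
                                     lambda_min_ratio = lambda_min_ratio), cm)
    },
    predictability = function(x) {
      node_predictability(npn_transform(x), gamma = gamma_pred)$r2
    }
  )
}

#' Case-dropping bootstrap of a node index
#'
#' Repeatedly re-estimates the full pipeline (transform, correlation,
#' EBIC-glasso, index) on random subsamples with a growing fraction of
#' respondents removed, and records the Pearson correlation between the
#' subsample and full-sample node-index vectors. Subsampling is without
#' replacement; each (proportion, replicate) cell has its own RNG stream
#' derived from the master seed so results do not depend on execution
#' order.
#'
#' @param x an [item_response_matrix()].
#' @param index one of `"strength"`, `"bridge_strength"`,
#'   `"predictability"`.
#' @param cm a [community_map()] (required for bridge strength).
#' @param proportions drop-proportion grid.
#' @param B bootstrap replicates per proportion.
#' @param seed master seed.
#' @param gamma EBIC hyperparameter for network selection.
#' @param gamma_pred EBIC hyperparameter for nodewise predictability.
#' @param n_lambda,lambda_min_ratio penalty-path settings passed to
#'   [select_network()].
#' @return An object of class `stability_result`: list with `index`,
#'   `proportions`, `correlations` (B x length(proportions) matrix),
#'   `full_index` (the full-sample vector), `B` and `seed`.
#' @export
case_drop_bootstrap <- function(x, index = c("strength", "bridge_strength",
                                             "predictability"),
                                cm = NULL,
                                proportions = seq(0.05, 0.75, by = 0.05),
                                B = 1000, seed = 1, gamma = 0.5,
                                gamma_pred = 0.25, n_lambda = 100,
                                lambda_min_ratio = 0.01) {
  stopifnot(inherits(x, "item_response_matrix"))
  index <- match.arg(index)
  if (index == "bridge_strength" && is.null(cm)) {
    stop("`cm` is required for bridge strength", call. = FALSE)
  }
  if (is.null(cm)) cm <- community_map(list(all = x$item_ids))
  p <- length(x$item_ids)
  n <- x$n
  sizes <- floor(n * (1 - proportions))
  if (any(sizes < p + 5)) {
    stop(sprintf(
      "drop proportion %.2f leaves %d cases; need at least p + 5 = %d",
      proportions[which.min(sizes)], min(sizes), p + 5), call. = FALSE)
  }
  proc <- index_procedures(cm, gamma, gamma_pred, n_lambda,
                           lambda_min_ratio)[[index]]
  full <- suppressWarnings(proc(x))

  cors <- matrix(NA_real_, B, length(proportions),
                 dimnames = list(NULL, sprintf("%.2f", proportions)))
  for (k in seq_along(proportions)) {
    m <- sizes[k]
    for (b in seq_len(B)) {
      set.seed(cell_seed(seed, (k - 1) * B + b))
      # dropping zero cases keeps the full sample (no permutation artifact)
      idx <- if (m == n) seq_len(n) else sample.int(n, m)
      sub <- item_response_matrix(x$values[idx, , drop = FALSE], x$item_ids)
      v <- tryCatch(suppressWarnings(proc(sub)), error = function(e) NULL)
      if (is.null(v) || sd(v) == 0 || sd(full) == 0) next
      cors[b, k] <- cor(v, full)
    }
  }
  structure(
    list(index = index, proportions = proportions, correlations = cors,
         full_index = full, B = B, seed = seed),
    class = "stability_result"
  )
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion at which at least `confidence` (default
#' 95%) of the bootstrap correlations between the subsample and
#' full-sample index remain at or above `cor_threshold` (default 0.7);
#' 0 when no grid proportion qualifies. Failed replicates (degenerate
#' subsample indices) count against the threshold.
#'
#' @param res a `stability_result` from [case_drop_bootstrap()].
#' @param cor_threshold correlation the subsample index must retain.
#' @param confidence required share of replicates meeting the threshold.
#' @return The CS-coefficient (a grid proportion, or 0).
#' @export
cs_coefficient <- function(res, cor_threshold = 0.7, confidence = 0.95) {
  stopifnot(inherits(res, "stability_result"))
  if (length(res$proportions) == 0) stop("empty proportion grid",
                                         call. = FALSE)
  ok <- colMeans(!is.na(res$correlations) &
                   res$correlations >= cor_threshold)
  qual <- res$proportions[ok >= confidence]
  if (length(qual) == 0) 0 else max(qual)
}

#' Interpret a CS-coefficient
#'
#' The conventional reading of the correlation-stability coefficient:
#' below 0.25 the index is too unstable to interpret; above 0.50 stability
#' is preferred; the band between (inclusive) is acceptable.
#'
#' @param cs CS-coefficient in `[0, 1]`.
#' @return One of `"insufficient"`, `"acceptable"`, `"preferred"`.
#' @export
interpret_cs <- function(cs) {
  stopifnot(cs >= 0, cs <= 1)
  if (cs < 0.25) "insufficient"
  else if (cs <= 0.50) "acceptable"
  else "preferred"
}

#' Stability results in long format
#'
#' @param res a `stability_result`.
#' @return Data frame `index, proportion, replicate, correlation`.
#' @export
stability_table <- function(res) {
  stopifnot(inherits(res, "stability_result"))
  data.frame(
    index = res$index,
    proportion = rep(res$proportions, each = res$B),
    replicate = rep(seq_len(res$B), times = length(res$proportions)),
    correlation = as.vector(res$correlations),
    stringsAsFactors = FALSE
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cs <- cs_coefficient(x)
  cat(sprintf(
    "<stability_result> index = %s, B = %d, grid %.2f..%.2f, CS = %.2f (%s)\n",
    x$index, x$B, min(x$proportions), max(x$proportions), cs,
    interpret_cs(cs)))
  invisible(x)
}
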