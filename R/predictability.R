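#' Nodewise predictability
#'
#' For each node, the proportion of its variance explained by all other
#' nodes: a LASSO regression of the node on the remaining columns is
#' fitted on the nonparanormal-transformed scale, the penalty is selected
#' by EBIC with hyperparameter `gamma` (0.25, the convention of nodewise
#' network estimation), and `R^2 = 1 - RSS/TSS` is reported against the
#' intercept-only model, clipped to `[0, 1]`. High predictability means a
#' symptom is largely determined by its neighbors in the network; low
#' predictability points to influences outside the network.
#'
#' @param z an `npn_matrix` from [npn_transform()] or a numeric matrix.
#' @param gamma EBIC hyperparameter for the nodewise penalty selection.
#' @return An object of class `predictability_table`: list with `r2`
#'   (named per-node vector) and `mean_r2`.
#' @export
node_predictability <- function(z, gamma = 0.25) {
  m <- if (inherits(z, "npn_matrix")) z$z else as.matrix(z)
  item_ids <- colnames(m)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(m)))
  n <- nrow(m); p <- ncol(m)
  if (p < 2) stop("need at least 2 items", call. = FALSE)
  if (n <= p) warning("n <= p; predictability estimates unstable",
                      call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate (constant) column(s): %s",
                 paste(item_ids[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r2 <- stats::setNames(numeric(p), item_ids)
  for (i in seq_len(p)) {
    y <- m[, i]
    X <- m[, -i, drop = FALSE]
    # explicit deep penalty path (glmnet's early exit would otherwise cap
    # the deviance ratio, keeping near-deterministic nodes from R^2 = 1)
    lmax <- max(abs(crossprod(scale(X), scale(y)))) / n
    lams <- exp(seq(log(lmax), log(lmax * 1e-7), length.out = 100))
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = lams)
    pred <- stats::predict(fit, newx = X)
    tss <- sum((y - mean(y))^2)
    rss <- colSums((y - pred)^2)
    df <- fit$df
    # EBIC for Gaussian regression: n log(RSS/n) + df log n + 2 gamma df log(p-1)
    ebic <- n * log(rss / n) + df * log(n) + 2 * gamma * df * log(p - 1)
    best <- which.min(ebic)
    r2[i] <- min(max(1 - rss[best] / tss, 0), 1)
  }
  structure(list(r2 = r2, mean_r2 = mean(r2)),
            class = "predictability_table")
}

#' @export
print.predictability_table <- function(x, ...) {
  cat(sprintf("<predictability_table> %d nodes, mean R2 = %.3f\n",
              length(x$r2), x$mean_r2))
  invisible(x)
}
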