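#' Nonparanormal (Gaussian-copula) transformation
#'
#' Maps each item's ordinal scores to the standard-normal scale through a
#' Winsorized empirical CDF: average ranks are converted to probabilities
#' `rank / (n + 1)`, truncated at `delta_n` and `1 - delta_n` with
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`, and passed through the
#' normal quantile function. Ties receive identical transformed values, so
#' the transform is invariant to any strictly increasing recoding of a
#' column. With only four response categories the truncation bound rarely
#' binds, but it guarantees finite output for arbitrary input.
#'
#' @param x an [item_response_matrix()] or a numeric matrix (items in
#'   columns).
#' @return An object of class `npn_matrix`: list with `z` (n x p numeric
#'   matrix), `item_ids` and `n`.
#' @export
npn_transform <- function(x) {
  m <- if (inherits(x, "item_response_matrix")) x$values else as.matrix(x)
  item_ids <- colnames(m)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(m)))
  n <- nrow(m)
  if (n < 3) stop("need at least 3 respondents", call. = FALSE)
  distinct <- apply(m, 2, function(v) length(unique(v)))
  if (any(distinct < 2)) {
    stop(sprintf("constant column(s): %s",
                 paste(item_ids[distinct < 2], collapse = ", ")),
         call. = FALSE)
  }
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  z <- apply(m, 2, function(v) {
    u <- rank(v, ties.method = "average") / (n + 1)
    qnorm(pmin(pmax(u, delta), 1 - delta))
  })
  dimnames(z) <- list(NULL, item_ids)
  structure(list(z = z, item_ids = item_ids, n = n), class = "npn_matrix")
}

#' Correlation matrix of transformed scores
#'
#' Pearson product-moment correlations of the nonparanormal-transformed
#' columns; together with [npn_transform()] this is the rank-based copula
#' correlation estimate feeding the graphical model. Exact symmetry is
#' enforced by averaging with the transpose.
#'
#' @param z an `npn_matrix` from [npn_transform()], or a numeric matrix.
#' @return An object of class `cor_matrix`: list with `r` (p x p), `n` and
#'   `item_ids`.
#' @export
correlation_matrix <- function(z) {
  if (inherits(z, "npn_matrix")) {
    m <- z$z; item_ids <- z$item_ids
  } else {
    m <- as.matrix(z)
    item_ids <- colnames(m)
    if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(m)))
  }
  n <- nrow(m); p <- ncol(m)
  if (n < p) warning("fewer observations than items; correlations unstable",
                     call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(item_ids[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r <- cor(m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(item_ids, item_ids)
  structure(list(r = r, n = n, item_ids = item_ids), class = "cor_matrix")
}

#' Write a labelled correlation matrix to CSV
#'
#' @param r a `cor_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(r, path) {
  stopifnot(inherits(r, "cor_matrix"))
  write.csv(as.data.frame(r$r), path, row.names = TRUE)
  invisible(path)
}
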