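test_that("full shrinkage yields the empty network", {
  set.seed(10)
  x <- matrix(rnorm(200 * 4), 200, 4)
  R <- cor(x)
  lam_max <- max(abs(R[upper.tri(R)]))
  est <- glasso_path(R, lam_max * 1.01)[[1]]
  expect_equal(est$n_edges, 0)
  expect_equal(est$K[upper.tri(est$K)], rep(0, 6))
})

test_that("the unpenalized fit recovers the inverse correlation matrix", {
  set.seed(11)
  x <- matrix(rnorm(500 * 3), 500, 3)
  R <- cor(x)
  est <- glasso_path(R, 0)[[1]]
  expect_equal(est$K, solve(R), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("penalized fits match an independent ADMM solution", {
  for (s in 1:3) {
    set.seed(100 + s)
    x <- matrix(rnorm(80 * 4), 80, 4) %*% matrix(rnorm(16), 4, 4)
    R <- cor(x)
    K_cd <- glasso_path(R, 0.1)[[1]]$K
    K_admm <- admm_glasso(R, 0.1)
    expect_equal(K_cd, K_admm, tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("EBIC reduces to BIC at gamma zero and penalizes edges monotonically", {
  set.seed(12)
  x <- matrix(rnorm(300 * 5), 300, 5)
  R <- cor(x)
  est <- glasso_path(R, 0.05)[[1]]
  E <- est$n_edges
  ll <- (300 / 2) * est$loglik_q
  expect_equal(ebic_score(est, R, n = 300, gamma = 0),
               -2 * ll + E * log(300))
  # extra gamma penalty is 4 E gamma log p
  expect_equal(ebic_score(est, R, n = 300, gamma = 0.5),
               ebic_score(est, R, n = 300, gamma = 0) + 4 * E * 0.5 * log(5))
  expect_error(ebic_score(est, R, n = 300, gamma = -1), "non-negative")
})

test_that("EBIC of the identity precision against r12 = 0.5 is the closed form", {
  # log det I = 0, tr(RI) = 2 => loglik = -(n/2) * 2 = -100, EBIC = 200
  K <- diag(2)
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  est <- structure(list(K = K, lambda = NA, n_edges = 0),
                   class = "precision_estimate")
  expect_equal(ebic_score(est, R, n = 100, gamma = 0.5), 200)
})

test_that("partial correlations follow the precision-matrix formula", {
  K <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partial_correlations(K)[1, 2], 0.5)
  expect_equal(partial_correlations(diag(3)), matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_error(partial_correlations(matrix(c(-1, 0, 0, 1), 2)), "positive")

  set.seed(13)
  A <- matrix(rnorm(49), 7, 7)
  K2 <- crossprod(A) + diag(7)
  W <- partial_correlations(K2)
  expect_identical(W, t(W))
  expect_true(all(abs(W[upper.tri(W)]) < 1))
  expect_equal(unname(diag(W)), rep(0, 7))
})

test_that("edge count is non-increasing along the penalty path", {
  set.seed(14)
  m <- make_truth(seed = 3)
  x <- sample_ordinal(m, 318, seed = 3)
  r <- correlation_matrix(npn_transform(x))
  lam_max <- max(abs(r$r[upper.tri(r$r)]))
  lambdas <- exp(seq(log(lam_max), log(0.01 * lam_max), length.out = 30))
  path <- glasso_path(r, lambdas)
  edges <- vapply(path, `[[`, numeric(1), "n_edges")
  expect_true(all(diff(edges) >= 0))  # path is solved from large to small
})

test_that("model selection defaults to gamma 0.50 and is deterministic", {
  m <- make_truth(seed = 4)
  x <- sample_ordinal(m, 318, seed = 4)
  r <- correlation_matrix(npn_transform(x))
  net1 <- select_network(r)
  net2 <- select_network(r)
  expect_equal(net1$gamma, 0.5)
  expect_identical(net1$W, net2$W)
  expect_identical(net1$lambda, net2$lambda)
  # weights are partial correlations of the selected precision fit
  expect_true(all(abs(net1$W) < 1))
  expect_equal(unname(diag(net1$W)), rep(0, 21))
  # selected model minimizes the recorded path EBIC
  expect_equal(net1$ebic, min(net1$path$ebic))
})

test_that("independent variables yield an (almost) empty selected network", {
  spurious <- 0
  for (s in 1:5) {
    set.seed(200 + s)
    x <- matrix(rnorm(1000 * 6), 1000, 6)
    net <- select_network(cor(x), n = 1000)
    spurious <- spurious + net$n_edges
  }
  expect_lte(spurious / 5, 1)
})

test_that("borderline non-PSD correlation inputs are repaired, with a message", {
  R <- matrix(0.99, 3, 3); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- -0.5  # indefinite
  expect_message(path <- glasso_path(R, 0.2), "repaired")
  expect_equal(path[[1]]$n_edges >= 0, TRUE)
})

test_that("edge lists and GraphML exports round-trip the network", {
  m <- make_truth(seed = 5)
  x <- sample_ordinal(m, 318, seed = 5)
  net <- select_network(correlation_matrix(npn_transform(x)))
  el <- edge_list(net)
  expect_equal(nrow(el), net$n_edges)
  expect_true(all(el$weight != 0))

  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, m$communities, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 21)
  expect_equal(igraph::ecount(g), net$n_edges)
  expect_setequal(unique(igraph::V(g)$community),
                  c("Stress", "Anxiety", "Depression"))
})
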