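stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full symptom-network pipeline
#'
#' Orchestrates ingestion, nonparanormal transformation, EBIC-glasso
#' network estimation, centrality and bridge statistics, nodewise
#' predictability, and (optionally) case-dropping bootstrap stability,
#' then writes the analysis artifacts: `edges.csv`, `node_metrics.csv`,
#' `stability.csv`, `summary.json`, a run log, and optionally a GraphML
#' export. All results are computed before anything is written, so a
#' failing stage leaves no partial outputs.
#'
#' @param input path to a response CSV, or an [item_response_matrix()].
#' @param communities a [community_map()], a path to a YAML/JSON map, or
#'   the preset name `"dass21"`.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param gamma EBIC hyperparameter for network selection.
#' @param gamma_pred EBIC hyperparameter for predictability.
#' @param n_lambda,lambda_min_ratio penalty-path settings.
#' @param stability_indices node indices to bootstrap; empty vector or
#'   `NULL` skips the stability stage. Skipped with a message below
#'   `min_n_stability` respondents unless `force_stability = TRUE`.
#' @param proportions,B,seed case-dropping bootstrap settings.
#' @param cor_threshold,confidence CS-coefficient settings.
#' @param min_n_stability smallest n at which stability runs by default.
#' @param force_stability run stability regardless of sample size.
#' @param graphml also write `network.graphml`.
#' @return A list with elements `data`, `network`, `metrics`,
#'   `predictability`, `stability` (named list of `stability_result`),
#'   `cs` (named list of CS coefficient + label), and `summary` (the
#'   content of `summary.json`).
#' @export
run_pipeline <- function(input, communities = "dass21", out_dir = NULL,
                         gamma = 0.5, gamma_pred = 0.25, n_lambda = 100,
                         lambda_min_ratio = 0.01,
                         stability_indices = c("strength", "bridge_strength",
                                               "predictability"),
                         proportions = seq(0.05, 0.75, by = 0.05),
                         B = 1000, seed = 1, cor_threshold = 0.7,
                         confidence = 0.95, min_n_stability = 100,
                         force_stability = FALSE, graphml = FALSE) {
  x <- stage("data_io", {
    if (inherits(input, "item_response_matrix")) input
    else read_responses(input)
  })
  cm <- stage("data_io", {
    if (inherits(communities, "community_map")) communities
    else if (identical(communities, "dass21")) {
      if (length(x$item_ids) == 21) dass21_communities(x$item_ids)
      else stop("dass21 preset needs 21 items")
    } else load_community_map(communities)
  })
  stage("data_io", validate_communities(cm, x$item_ids))

  z <- stage("npn_transform", npn_transform(x))
  r <- stage("correlation", correlation_matrix(z))
  net <- stage("ggm", select_network(r, gamma = gamma, n_lambda = n_lambda,
                                     lambda_min_ratio = lambda_min_ratio))
  pred <- stage("predictability", node_predictability(z, gamma = gamma_pred))
  metrics <- stage("centrality",
                   suppressWarnings(node_metrics(net, cm, pred)))

  stab <- list(); cs <- list()
  do_stab <- length(stability_indices) > 0 && !is.null(stability_indices)
  if (do_stab && x$n < min_n_stability && !force_stability) {
    message(sprintf(
      "n = %d < %d: stability stage skipped (use force_stability = TRUE)",
      x$n, min_n_stability))
    do_stab <- FALSE
  }
  if (do_stab) {
    for (ix in stability_indices) {
      stab[[ix]] <- stage("stability", case_drop_bootstrap(
        x, index = ix, cm = cm, proportions = proportions, B = B,
        seed = seed, gamma = gamma, gamma_pred = gamma_pred,
        n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio))
      csv <- cs_coefficient(stab[[ix]], cor_threshold, confidence)
      cs[[ix]] <- list(cs = csv, label = interpret_cs(csv))
    }
  }

  summary <- list(
    n_read = attr(x, "n_read") %||% x$n,
    n_dropped = attr(x, "n_dropped") %||% 0L,
    n_retained = x$n,
    p = length(x$item_ids),
    gamma = gamma,
    gamma_pred = gamma_pred,
    n_lambda = n_lambda,
    lambda_min_ratio = lambda_min_ratio,
    selected_lambda = net$lambda,
    ebic = net$ebic,
    n_edges = net$n_edges,
    mean_predictability = pred$mean_r2,
    stability = lapply(cs, function(e) list(cs = e$cs, label = e$label)),
    bootstrap = if (do_stab) {
      list(B = B, seed = seed, proportions = proportions,
           cor_threshold = cor_threshold, confidence = confidence)
    } else NULL
  )

  if (!is.null(out_dir)) {
    stage("report", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(edge_list(net), file.path(out_dir, "edges.csv"),
                row.names = FALSE)
      write.csv(metrics, file.path(out_dir, "node_metrics.csv"),
                row.names = FALSE)
      if (length(stab) > 0) {
        write.csv(do.call(rbind, lapply(stab, stability_table)),
                  file.path(out_dir, "stability.csv"), row.names = FALSE)
      }
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      if (graphml) write_graphml(net, cm, file.path(out_dir,
                                                    "network.graphml"))
      writeLines(
        c(sprintf("distressnet run %s", format(Sys.time(), "%Y-%m-%d %H:%M")),
          sprintf("n_read=%d n_dropped=%d n_retained=%d",
                  summary$n_read, summary$n_dropped, summary$n_retained),
          sprintf("gamma=%.2f n_lambda=%d lambda_min_ratio=%.3f",
                  gamma, n_lambda, lambda_min_ratio),
          sprintf("selected_lambda=%.6g n_edges=%d ebic=%.3f",
                  net$lambda, net$n_edges, net$ebic),
          sprintf("mean_predictability=%.4f", pred$mean_r2),
          if (length(cs) > 0) {
            sprintf("cs_%s=%.2f (%s)", names(cs),
                    vapply(cs, `[[`, numeric(1), "cs"),
                    vapply(cs, `[[`, character(1), "label"))
          } else "stability: skipped"),
        file.path(out_dir, "run.log"))
    })
  }

  invisible(list(data = x, communities = cm, network = net,
                 metrics = metrics, predictability = pred,
                 stability = stab, cs = cs, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot the symptom network
#'
#' A minimal static rendering: communities as vertex colors, edge width
#' proportional to the absolute partial correlation.
#'
#' @param net a `ggm_network`.
#' @param cm a [community_map()].
#' @param ... passed to [igraph::plot.igraph()].
#' @return The igraph object, invisibly.
#' @export
plot_network <- function(net, cm, ...) {
  stopifnot(inherits(net, "ggm_network"))
  validate_communities(cm, net$item_ids)
  g <- igraph::graph_from_adjacency_matrix(abs(net$W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comm <- factor(cm$assignment[net$item_ids], levels = cm$communities)
  igraph::V(g)$color <- grDevices::hcl.colors(nlevels(comm),
                                              "Set 2")[as.integer(comm)]
  igraph::plot.igraph(g, edge.width = 5 * igraph::E(g)$weight,
                      vertex.label = net$item_ids, ...)
  invisible(g)
}
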