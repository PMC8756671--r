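#' Signed co-occurrence network of taxa from abundance profiles
#'
#' Computes pairwise correlations between taxon abundance profiles across
#' samples and keeps an edge where the correlation magnitude reaches `r_min`
#' and a permutation test (shuffling one profile over samples, the same fixed
#' permutation set for every pair) gives `p <= alpha`. Edge sign is the sign
#' of the correlation: positive edges suggest shared niches or cooperation,
#' negative edges competition or exclusion. Taxa with zero variance cannot be
#' correlated and are dropped with a message.
#'
#' @param abundance Numeric matrix or data frame, taxa x samples (taxa in
#'   rows, rownames = taxon ids), or a long tibble with columns `taxon`,
#'   `sample`, `abundance`.
#' @param method `"spearman"` (default, robust to abundance skew) or
#'   `"pearson"`.
#' @param r_min Minimum absolute correlation for an edge (default 0.8).
#' @param alpha Permutation p-value cutoff (default 0.05).
#' @param n_perm Number of sample permutations (default 1000).
#' @param seed Integer seed making the permutation set, and hence the edge
#'   set, reproducible.
#' @return An object of class `cooc_network`: list with `edges` (tibble
#'   `taxon_a`, `taxon_b`, `r`, `sign`, `p_perm`), `nodes` (tibble `taxon`,
#'   `mean_abundance`, `degree`), `params`, and `graph` (an [igraph] graph
#'   with node size attribute proportional to degree).
#' @examples
#' m <- rbind(a = 1:10, b = (1:10) * 2, c = 10:1)
#' net <- build_network(m, method = "pearson", n_perm = 200, seed = 1)
#' tidy(net)
#' @export
build_network <- function(abundance, method = c("spearman", "pearson"),
                          r_min = 0.8, alpha = 0.05, n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  mat <- as_taxa_matrix(abundance)
  if (ncol(mat) < 3L) abort("need at least 3 samples to correlate profiles")
  keep <- apply(mat, 1L, function(x) sd(x) > 0)
  if (any(!keep)) {
    inform(paste0("dropping zero-variance taxa: ",
                  paste(rownames(mat)[!keep], collapse = ", ")))
    mat <- mat[keep, , drop = FALSE]
  }
  taxa <- rownames(mat)
  n_tax <- nrow(mat)
  n_s <- ncol(mat)
  # rank-transform once for spearman so permutations reduce to pearson on ranks
  prof <- if (method == "spearman") t(apply(mat, 1L, rank)) else mat
  prof <- prof - rowMeans(prof)
  norms <- sqrt(rowSums(prof^2))
  prof <- prof / norms
  robs <- tcrossprod(prof) # taxa x taxa correlation matrix
  perms <- withr_seed(seed, {
    matrix(replicate(n_perm, sample.int(n_s)), nrow = n_perm, byrow = TRUE)
  })
  edges <- NULL
  if (n_tax >= 2L) {
    pairs <- which(upper.tri(robs), arr.ind = TRUE)
    pvals <- vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      x <- prof[i, ]
      y <- prof[j, ]
      rp <- as.numeric(matrix(y[t(perms)], nrow = n_s) |> crossprod(x))
      (1 + sum(abs(rp) >= abs(robs[i, j]) - 1e-12)) / (n_perm + 1)
    }, numeric(1))
    edges <- tibble(
      taxon_a = taxa[pairs[, 1L]],
      taxon_b = taxa[pairs[, 2L]],
      r = robs[pairs],
      p_perm = pvals
    ) |>
      filter(abs(.data$r) >= r_min, .data$p_perm <= alpha) |>
      mutate(sign = ifelse(.data$r >= 0, "positive", "negative")) |>
      select("taxon_a", "taxon_b", "r", "sign", "p_perm") |>
      arrange(.data$taxon_a, .data$taxon_b)
  } else {
    edges <- tibble(taxon_a = character(), taxon_b = character(),
                    r = numeric(), sign = character(), p_perm = numeric())
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_a", "taxon_b", "r", "sign", "p_perm")],
    directed = FALSE,
    vertices = data.frame(name = taxa)
  )
  deg <- igraph::degree(g)
  igraph::V(g)$size <- deg
  nodes <- tibble(taxon = taxa,
                  mean_abundance = rowMeans(mat),
                  degree = as.integer(deg[taxa]))
  structure(
    list(edges = edges, nodes = nodes, graph = g,
         params = list(method = method, r_min = r_min, alpha = alpha,
                       n_perm = n_perm, seed = seed, n_samples = n_s)),
    class = "cooc_network"
  )
}

as_taxa_matrix <- function(x) {
  if (is.data.frame(x) && all(c("taxon", "sample", "abundance") %in% names(x))) {
    wide <- tidyr::pivot_wider(x, id_cols = "taxon", names_from = "sample",
                               values_from = "abundance")
    m <- as.matrix(wide[, -1L])
    rownames(m) <- wide$taxon
    return(m)
  }
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("taxon_", seq_len(nrow(m)))
  m
}

# evaluate expr under a local RNG state; seed = NULL draws from the ambient
# stream (single-stream Monte-Carlo designs: re-seeding every replicate with
# consecutive integers leaves detectable structure in the first draws)
withr_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Topology statistics of a co-occurrence network
#'
#' Edge counts by sign, positive fraction, mean degree and the global
#' (sign-blind) clustering coefficient (3 x triangles / connected triples) —
#' the quantities compared between high-glucose and glucose-free treatment
#' networks.
#'
#' @param graph A `cooc_network` object.
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_positive`, `n_negative`,
#'   `positive_fraction`, `mean_degree`, `global_clustering`.
#' @export
network_stats <- function(graph) {
  stopifnot(inherits(graph, "cooc_network"))
  e <- graph$edges
  n_nodes <- nrow(graph$nodes)
  n_edges <- nrow(e)
  n_pos <- sum(e$sign == "positive")
  cc <- igraph::transitivity(graph$graph, type = "global")
  tibble(
    n_nodes = n_nodes,
    n_edges = n_edges,
    n_positive = n_pos,
    n_negative = n_edges - n_pos,
    positive_fraction = if (n_edges > 0) n_pos / n_edges else NA_real_,
    mean_degree = if (n_nodes > 0) 2 * n_edges / n_nodes else 0,
    global_clustering = if (is.nan(cc)) 0 else cc
  )
}

#' @export
print.cooc_network <- function(x, ...) {
  s <- network_stats(x)
  cat("<cooc_network> ", s$n_nodes, " taxa, ", s$n_edges, " edges (",
      s$n_positive, " positive / ", s$n_negative, " negative), ",
      x$params$method, ", |r| >= ", x$params$r_min, ", alpha = ",
      x$params$alpha, "\n", sep = "")
  invisible(x)
}

#' Tidy the edge list of a co-occurrence network
#'
#' @param x A `cooc_network`.
#' @param ... Unused.
#' @return Tibble `taxon_a`, `taxon_b`, `r`, `sign`, `p_perm`.
#' @method tidy cooc_network
#' @export
tidy.cooc_network <- function(x, ...) x$edges

#' One-row topology summary of a co-occurrence network
#'
#' @param x A `cooc_network`.
#' @param ... Unused.
#' @return See [network_stats()].
#' @method glance cooc_network
#' @export
glance.cooc_network <- function(x, ...) network_stats(x)

#' Plot a co-occurrence network
#'
#' Green positive and red negative edges, node size proportional to the
#' number of connections.
#'
#' @param object A `cooc_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cooc_network
#' @export
autoplot.cooc_network <- function(object, ...) {
  lay <- igraph::layout_with_fr(object$graph,
                                coords = igraph::layout_in_circle(object$graph))
  pos <- tibble(taxon = igraph::V(object$graph)$name,
                x = lay[, 1], y = lay[, 2]) |>
    left_join(object$nodes, by = "taxon")
  seg <- object$edges |>
    left_join(pos |> select("taxon", xa = "x", ya = "y"),
              by = c(taxon_a = "taxon")) |>
    left_join(pos |> select("taxon", xb = "x", yb = "y"),
              by = c(taxon_b = "taxon"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$sign)) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree)) +
    ggplot2::scale_colour_manual(
      values = c(positive = "forestgreen", negative = "firebrick")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "correlation", size = "connections")
}

#' Write a co-occurrence network to GraphML
#'
#' @param graph A `cooc_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}
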