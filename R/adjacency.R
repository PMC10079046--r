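#' Province adjacency graphs
#'
#' Neighbourhood structure drives both the conditional-autoregressive (CAR)
#' spatial terms and the graph-diffusion spatial kernel. Graphs are handled as
#' undirected `igraph` objects with named vertices; helpers generate the three
#' synthetic topologies, read/write plain two-column edge lists, and build the
#' precision matrices the spatial and temporal smoothers need.
#'
#' @param n_provinces number of provinces (vertices), at least 4.
#' @param model `"grid"` (near-square lattice), `"ring"`, or `"random-planar"`
#'   (random geometric graph forced connected by nearest-neighbour edges).
#' @param seed RNG seed, used only by `"random-planar"`.
#' @param labels optional vertex names; defaults to `"P01"`, `"P02"`, ...
#' @return An undirected connected `igraph` with named vertices.
#' @export
make_adjacency <- function(n_provinces, model = c("grid", "ring", "random-planar"),
                           seed = 1, labels = NULL) {
  model <- match.arg(model)
  if (n_provinces < 4) abort("need at least 4 provinces")
  labels <- labels %||% sprintf("P%02d", seq_len(n_provinces))
  g <- switch(model,
    grid = {
      nr <- floor(sqrt(n_provinces))
      nc <- ceiling(n_provinces / nr)
      full <- igraph::make_lattice(c(nr, nc))
      igraph::induced_subgraph(full, seq_len(n_provinces))
    },
    ring = igraph::make_ring(n_provinces),
    `random-planar` = with_seed(seed, {
      xy <- cbind(runif(n_provinces), runif(n_provinces))
      d <- as.matrix(dist(xy))
      thr <- quantile(d[upper.tri(d)], 0.25)
      adj <- d <= thr & d > 0
      g0 <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      # knit disconnected components together through nearest inter-component pairs
      while (!igraph::is_connected(g0)) {
        comp <- igraph::components(g0)$membership
        d2 <- d
        same <- outer(comp, comp, "==")
        d2[same] <- Inf
        idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
        g0 <- igraph::add_edges(g0, idx)
      }
      igraph::simplify(g0)
    })
  )
  igraph::V(g)$name <- labels
  if (!igraph::is_connected(g)) abort("generated adjacency graph is not connected")
  g
}

#' @rdname make_adjacency
#' @param graph an `igraph` adjacency graph.
#' @param path two-column CSV edge list (`from,to`).
#' @export
write_adjacency <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.csv(data.frame(from = el[, 1], to = el[, 2]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname make_adjacency
#' @export
read_adjacency <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(df))) abort("edge list needs `from` and `to` columns")
  g <- igraph::graph_from_data_frame(df[, c("from", "to")], directed = FALSE)
  g <- igraph::simplify(g)
  if (!igraph::is_connected(g)) abort("adjacency graph read from edge list is not connected")
  g
}

# Unscaled intrinsic CAR (Besag) precision D - W as a dense symmetric matrix,
# vertices in graph order.
icar_structure <- function(graph) {
  w <- as.matrix(igraph::as_adjacency_matrix(graph))
  diag(rowSums(w)) - w
}

# Geometric-mean marginal variance of the sum-to-zero constrained GMRF with
# precision Q (rank deficiency 1) -- the BYM2-style scaling constant.
gmrf_scale_factor <- function(Q) {
  n <- nrow(Q)
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  # pseudo-inverse marginal variances under the sum-to-zero constraint
  v <- rowSums(sweep(e$vectors[, pos, drop = FALSE]^2, 2, e$values[pos], "/"))
  exp(mean(log(v)))
}

# Scaled Besag structure: (D - W) * scale so the constrained field has
# geometric-mean marginal variance 1 at unit precision parameter.
icar_structure_scaled <- function(graph) {
  Q <- icar_structure(graph)
  Q * gmrf_scale_factor(Q)
}

# RW2 structure matrix t(D2) %*% D2 with D2 the second-difference operator.
rw2_structure <- function(n_years) {
  if (n_years < 3) abort("RW2 needs at least 3 time points")
  d2 <- diff(diag(n_years), differences = 2)
  crossprod(d2)
}

# Sample a zero-mean GMRF with (possibly singular) precision tau * Q under the
# sum-to-zero constraint, via eigen-decomposition of Q.
sample_constrained_gmrf <- function(Q, sd_scale, n = 1) {
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  u <- e$vectors[, pos, drop = FALSE]
  lam <- e$values[pos]
  z <- matrix(rnorm(sum(pos) * n), sum(pos), n) / sqrt(lam)
  x <- u %*% z * sd_scale
  sweep(x, 2, colMeans(x)) # enforce sum-to-zero exactly
}
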