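#' Construct a binary graph
#'
#' A simple undirected graph on labelled nodes, stored as a symmetric 0/1
#' adjacency matrix with zero diagonal.
#'
#' @param adj square numeric or logical matrix; must be symmetric with an
#'   empty diagonal. Dimnames, if absent, default to `v1..vn`.
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adj) {
  adj <- (adj != 0) * 1L
  check_that(
    "adjacency must be a square matrix" = is.matrix(adj) &&
      nrow(adj) == ncol(adj),
    "adjacency must be symmetric" = identical(adj, t(adj)),
    "self-loops are not allowed" = all(diag(adj) == 0)
  )
  if (is.null(rownames(adj))) {
    labels <- paste0("v", seq_len(nrow(adj)))
    dimnames(adj) <- list(labels, labels)
  }
  structure(list(adj = adj, labels = rownames(adj)), class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges", n_nodes(x), n_edges(x)))
  iso <- sum(degrees(x) == 0)
  if (iso > 0) cat(sprintf(" (%d isolated node%s)", iso, if (iso > 1) "s" else ""))
  cat("\n")
  invisible(x)
}

#' Node count, edge count, degree sequence, edge list
#'
#' Small accessors for [binary_graph()] objects. `graph_edges()` returns the
#' unordered node-index pairs as a two-column matrix with `i < j`.
#'
#' @param g a `binary_graph`.
#' @return See each accessor.
#' @export
n_nodes <- function(g) nrow(g$adj)

#' @rdname n_nodes
#' @export
n_edges <- function(g) sum(g$adj) / 2

#' @rdname n_nodes
#' @export
degrees <- function(g) rowSums(g$adj)

#' @rdname n_nodes
#' @export
graph_edges <- function(g) {
  which(upper.tri(g$adj) & g$adj > 0, arr.ind = TRUE, useNames = FALSE)
}

is_connected_graph <- function(g) {
  n <- n_nodes(g)
  if (n <= 1) return(TRUE)
  seen <- bfs_distances(g$adj, 1L)
  all(is.finite(seen))
}

#' Binarize an adjacency matrix by weight threshold
#'
#' Edge `(i, j)` is kept iff its weight is at least `threshold` (ties at the
#' threshold survive). Isolated nodes violate the network-construction
#' principle; they are reported through the `isolated` attribute and by
#' [threshold_sweep()], never silently repaired.
#'
#' @param adj an `mi_adjacency` or symmetric weight matrix.
#' @param threshold non-negative weight cutoff.
#' @return A [binary_graph()] with attribute `isolated` (character vector of
#'   isolated node labels, possibly empty).
#' @export
binarize_by_threshold <- function(adj, threshold) {
  check_that("threshold must be a non-negative number" =
               is.numeric(threshold) && length(threshold) == 1 && threshold >= 0)
  v <- adjacency_values(adj)
  a <- (v >= threshold) * 1L
  diag(a) <- 0L
  g <- binary_graph(a)
  attr(g, "isolated") <- g$labels[degrees(g) == 0]
  g
}

#' Binarize an adjacency matrix at a fixed mean degree
#'
#' Keeps the `m = round(n * K / 2)` largest-weight entries as edges (half-up
#' rounding), so that all networks compared share the same node and edge
#' counts and differ only in their spatial arrangement. Ties are broken by
#' lexicographic node-index order for determinism.
#'
#' @param adj an `mi_adjacency` or symmetric weight matrix.
#' @param K target mean degree; `n * K / 2` must not exceed the number of
#'   node pairs.
#' @return A [binary_graph()] with exactly `round(n * K / 2)` edges.
#' @export
binarize_by_degree <- function(adj, K) {
  v <- adjacency_values(adj)
  n <- nrow(v)
  m <- floor(n * K / 2 + 0.5)   # explicit half-up rounding
  check_that(
    "K must be >= 1" = K >= 1,
    "requested edge count exceeds the number of node pairs" =
      m <= n * (n - 1) / 2
  )
  ut <- which(upper.tri(v), arr.ind = TRUE, useNames = FALSE)
  w <- v[ut]
  o <- order(-w, ut[, 1], ut[, 2])
  a <- matrix(0L, n, n, dimnames = dimnames(v))
  sel <- ut[o[seq_len(m)], , drop = FALSE]
  a[sel] <- 1L
  a[sel[, c(2, 1), drop = FALSE]] <- 1L
  binary_graph(a)
}

#' Clustering coefficient
#'
#' For each node `i` with `K_i` neighbours, `C_i = 2 E_i / (K_i (K_i - 1))`
#' where `E_i` counts the links among the neighbours; nodes of degree < 2
#' contribute `C_i = 0`. The graph value is the mean over all nodes.
#'
#' @param g a [binary_graph()] with at least one node.
#' @return `C` in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  check_that("g must be a binary_graph" = inherits(g, "binary_graph"),
             "graph must have at least one node" = n_nodes(g) >= 1)
  a <- g$adj
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2          # E_i per node
  denom <- deg * (deg - 1) / 2
  ci <- ifelse(denom > 0, tri / denom, 0)
  mean(ci)
}

# Unweighted single-source shortest paths (BFS); Inf marks unreachable.
bfs_distances <- function(a, src) {
  n <- nrow(a)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !is.finite(dist))
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Characteristic path length
#'
#' Mean shortest-path length in hops over all ordered node pairs (breadth
#' first search; equivalent to Dijkstra with unit weights). If some pairs
#' are unreachable the mean is taken over the reachable pairs only and the
#' `disconnected` attribute of the result is set.
#'
#' @param g a [binary_graph()] with at least 2 nodes and at least one edge.
#' @return `L >= 1` with logical attribute `disconnected`.
#' @export
characteristic_path_length <- function(g) {
  check_that("g must be a binary_graph" = inherits(g, "binary_graph"),
             "graph must have at least 2 nodes" = n_nodes(g) >= 2)
  if (n_edges(g) == 0) {
    stop("graph has no edges; characteristic path length is undefined",
         call. = FALSE)
  }
  n <- n_nodes(g)
  total <- 0
  count <- 0L
  unreachable <- FALSE
  for (i in seq_len(n)) {
    di <- bfs_distances(g$adj, i)[-i]
    fin <- is.finite(di)
    if (!all(fin)) unreachable <- TRUE
    total <- total + sum(di[fin])
    count <- count + sum(fin)
  }
  L <- total / count
  attr(L, "disconnected") <- unreachable
  L
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Repeatedly picks two edges `(a, b)` and `(c, d)` and rewires them to
#' `(a, d)` and `(c, b)`, rejecting any move that would create a self-loop
#' or duplicate edge, until `n_swaps` swaps have been accepted. Every node's
#' degree is exactly preserved. If the graph admits too few valid moves the
#' procedure returns after a bounded attempt budget with a warning.
#'
#' Each accepted swap relocates two edges and two non-edges, so the mixing
#' budget scales with the movable pairs: the default is 10 x
#' `min(edges, non-edges)`. A complete graph has no non-edges, admits no
#' move, and is returned unchanged.
#'
#' @param g a [binary_graph()] with at least 2 edges.
#' @param n_swaps accepted swaps to perform
#'   (default `10 * min(n_edges, n_non_edges)`).
#' @param seed integer seed; output is deterministic given the seed.
#' @param max_attempts attempt cap (default `200 * n_swaps`, at least 1000).
#' @return A rewired `binary_graph` with the same degree sequence.
#' @export
maslov_sneppen_rewire <- function(g, n_swaps = NULL, seed = 0,
                                  max_attempts = NULL) {
  check_that("g must be a binary_graph" = inherits(g, "binary_graph"),
             "graph must have at least 2 edges" = n_edges(g) >= 2)
  n <- n_nodes(g)
  np <- n * (n - 1) / 2
  movable <- min(n_edges(g), np - n_edges(g))
  n_swaps <- n_swaps %||% (10 * movable)
  max_attempts <- max_attempts %||% max(1000, 200 * n_swaps)
  # a double-edge swap relocates two edges and two non-edges, so a graph
  # with fewer than two movable pairs on either side is frozen
  if (n_swaps == 0 || movable < 2) return(binary_graph(g$adj))
  # a double-edge swap on the graph is a double-edge swap on its complement,
  # so proposals are drawn from whichever side is sparser: acceptance stays
  # high at any density
  use_complement <- n_edges(g) > np / 2
  a <- if (use_complement) {
    ac <- 1L - g$adj
    diag(ac) <- 0L
    dimnames(ac) <- dimnames(g$adj)
    ac
  } else {
    g$adj
  }
  el <- which(upper.tri(a) & a > 0, arr.ind = TRUE, useNames = FALSE)
  m <- nrow(el)
  with_seed(seed, {
    accepted <- 0L
    attempts <- 0L
    # proposal randomness is drawn in chunks; the accept/reject loop itself
    # stays sequential because each move depends on the current graph
    chunk <- as.integer(max(256, min(4 * n_swaps, 65536)))
    idx <- chunk
    p1 <- p2 <- flip <- NULL
    while (accepted < n_swaps && attempts < max_attempts) {
      if (idx >= chunk) {
        p1 <- sample.int(m, chunk, replace = TRUE)
        p2 <- sample.int(m, chunk, replace = TRUE)
        flip <- stats::runif(chunk) < 0.5
        idx <- 0L
      }
      idx <- idx + 1L
      attempts <- attempts + 1L
      i1 <- p1[idx]; i2 <- p2[idx]
      if (i1 == i2) next
      va <- el[i1, 1]; vb <- el[i1, 2]
      # orient the second edge at random so both pairings are proposable
      if (flip[idx]) {
        vc <- el[i2, 1]; vd <- el[i2, 2]
      } else {
        vc <- el[i2, 2]; vd <- el[i2, 1]
      }
      if (va == vc || va == vd || vb == vc || vb == vd) next
      if (a[va, vd] == 1L || a[vc, vb] == 1L) next
      a[va, vb] <- a[vb, va] <- 0L
      a[vc, vd] <- a[vd, vc] <- 0L
      a[va, vd] <- a[vd, va] <- 1L
      a[vc, vb] <- a[vb, vc] <- 1L
      el[i1, ] <- if (va < vd) c(va, vd) else c(vd, va)
      el[i2, ] <- if (vc < vb) c(vc, vb) else c(vb, vc)
      accepted <- accepted + 1L
    }
    if (accepted < n_swaps) {
      warning(sprintf("attempt cap reached after %d of %d swaps",
                      accepted, n_swaps))
    }
  })
  if (use_complement) {
    a <- 1L - a
    diag(a) <- 0L
    dimnames(a) <- dimnames(g$adj)
  }
  binary_graph(a)
}

#' Small-world index against a degree-preserving null ensemble
#'
#' Computes `C` and `L` of the graph and of `n_nulls` independent
#' Maslov-Sneppen rewirings, and the small-world index
#' `sigma = (C / C_rand) / (L / L_rand)` with the ensemble means as
#' reference; `sigma > 1` marks small-world organization. Null seeds are
#' derived as `seed + null index`. If the nulls are triangle-free
#' (`C_rand = 0`) sigma is undefined and reported as `NA`. For a complete
#' graph no degree-preserving move exists, the nulls equal the graph itself
#' and `sigma` is exactly 1.
#'
#' @param g a connected (or at least isolate-free) [binary_graph()].
#' @param n_nulls size of the null ensemble (default 250).
#' @param seed master integer seed for the ensemble.
#' @param swap_multiplier accepted swaps per null, in units of the movable
#'   (edge or non-edge, whichever is fewer) pair count.
#' @return An object of class `small_world` with fields `C`, `L`, `C_rand`,
#'   `L_rand`, `sigma`, `n_nulls`, `disconnected`.
#' @examples
#' g <- generate_ws_graph(19, 4, 0.1, seed = 1)
#' small_world(g, n_nulls = 25, seed = 1)
#' @export
small_world <- function(g, n_nulls = 250, seed = 0, swap_multiplier = 10) {
  check_that("g must be a binary_graph" = inherits(g, "binary_graph"),
             "n_nulls must be >= 1" = n_nulls >= 1)
  C <- clustering_coefficient(g)
  L <- characteristic_path_length(g)
  np <- n_nodes(g) * (n_nodes(g) - 1) / 2
  n_swaps <- swap_multiplier * min(n_edges(g), np - n_edges(g))
  cr <- numeric(n_nulls)
  lr <- numeric(n_nulls)
  for (i in seq_len(n_nulls)) {
    null <- maslov_sneppen_rewire(g, n_swaps = n_swaps, seed = seed + i)
    cr[i] <- clustering_coefficient(null)
    lr[i] <- characteristic_path_length(null)
  }
  C_rand <- mean(cr)
  L_rand <- mean(lr)
  sigma <- if (C_rand > 0) (C / C_rand) / (as.numeric(L) / L_rand) else NA_real_
  structure(
    list(C = C, L = as.numeric(L), C_rand = C_rand, L_rand = L_rand,
         sigma = sigma, n_nulls = n_nulls,
         disconnected = isTRUE(attr(L, "disconnected"))),
    class = "small_world"
  )
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf("Small-world analysis (%d nulls)%s\n", x$n_nulls,
              if (x$disconnected) " [disconnected: L over reachable pairs]" else ""))
  cat(sprintf("  C = %.4f  (C_rand = %.4f)\n", x$C, x$C_rand))
  cat(sprintf("  L = %.4f  (L_rand = %.4f)\n", x$L, x$L_rand))
  cat(sprintf("  sigma = %s\n",
              if (is.na(x$sigma)) "undefined (triangle-free nulls)"
              else sprintf("%.4f", x$sigma)))
  invisible(x)
}

#' Threshold sweep of network metrics
#'
#' Binarizes a weighted adjacency matrix at each threshold of an ascending
#' series and computes the small-world metrics wherever the resulting
#' network has no isolated node; thresholds producing isolated nodes are
#' flagged invalid and left uncomputed, following the no-isolated-node
#' construction principle.
#'
#' @param adj an `mi_adjacency` or symmetric weight matrix.
#' @param thresholds strictly increasing numeric vector
#'   (default `seq(0.15, 0.35, by = 0.01)`).
#' @param n_nulls null-ensemble size per threshold.
#' @param seed master integer seed.
#' @return A data frame of class `threshold_sweep` with one row per
#'   threshold: `threshold`, `n_edges`, `n_isolated`, `valid`, `C`, `L`,
#'   `C_rand`, `L_rand`, `sigma`, `disconnected`.
#' @export
threshold_sweep <- function(adj, thresholds = seq(0.15, 0.35, by = 0.01),
                            n_nulls = 250, seed = 0) {
  check_that("thresholds must be strictly increasing" =
               length(thresholds) >= 1 && all(diff(thresholds) > 0))
  rows <- lapply(seq_along(thresholds), function(ti) {
    tt <- thresholds[ti]
    g <- binarize_by_threshold(adj, tt)
    iso <- attr(g, "isolated")
    row <- data.frame(threshold = tt, n_edges = n_edges(g),
                      n_isolated = length(iso), valid = length(iso) == 0,
                      C = NA_real_, L = NA_real_, C_rand = NA_real_,
                      L_rand = NA_real_, sigma = NA_real_,
                      disconnected = NA)
    if (length(iso) == 0 && n_edges(g) > 0) {
      sw <- small_world(g, n_nulls = n_nulls, seed = seed + 1000L * ti)
      row$C <- sw$C; row$L <- sw$L
      row$C_rand <- sw$C_rand; row$L_rand <- sw$L_rand
      row$sigma <- sw$sigma; row$disconnected <- sw$disconnected
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' Convert a binary graph to an igraph object
#'
#' @param g a [binary_graph()].
#' @return An `igraph` graph with node names.
#' @export
as_igraph <- function(g) {
  check_that("g must be a binary_graph" = inherits(g, "binary_graph"))
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
}

#' Export a binary graph to Pajek or GraphML
#'
#' @param g a [binary_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "pajek")
  invisible(path)
}

#' @rdname write_pajek
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}
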