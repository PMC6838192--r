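#' Grid graph for circuit-theory connectivity
#'
#' Converts a resistance surface into a weighted graph with 8-neighbor
#' connectivity (the average-resistance scheme): an orthogonal edge between
#' cells i and j has resistance `(r_i + r_j) / 2`; a diagonal edge has
#' resistance `sqrt(2) * (r_i + r_j) / 2`, reflecting the longer span.
#' Nodata cells are excluded; each locality maps to the single cell
#' containing it.
#'
#' @param resistance `land_grid` of per-cell resistances (all > 0).
#' @param localities data.frame with columns `name`, `x`, `y`.
#' @return object of class `grid_graph`.
#' @export
build_grid_graph <- function(resistance, localities) {
  tmpl <- graph_template(resistance, localities)
  graph_set_resistance(tmpl, resistance)
}

#' @rdname build_grid_graph
#' @details `graph_template()` builds the value-independent part (node
#'   indexing, edge list, focal nodes, connected components); pairing it with
#'   `graph_set_resistance()` lets optimizers re-weight the same landscape
#'   cheaply. `build_grid_graph()` is the one-shot combination.
#' @export
graph_template <- function(resistance, localities) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 2L) stop("fewer than 2 non-nodata cells")
  node_id <- matrix(NA_integer_, nr, nc)
  node_id[ok] <- seq_len(n)

  # edges by shifting the node-id matrix; (dr, dc) in {(0,1),(1,0),(1,1),(1,-1)}
  ei <- integer(0); ej <- integer(0); dg <- logical(0)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- node_id[r1, c1, drop = FALSE]
    b <- node_id[r1 + dr, c1 + dc, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    ei <- c(ei, a[keep]); ej <- c(ej, b[keep])
    dg <- c(dg, rep(dr != 0L && dc != 0L, sum(keep)))
  }

  # focal nodes
  if (anyDuplicated(localities$name)) stop("duplicate locality names")
  cells <- locate_cells(land_grid(v, resistance$cell_size, resistance$origin),
                        localities$x, localities$y)
  foc <- node_id[cells]
  if (anyNA(foc))
    stop("localities fall on nodata cells: ",
         paste(localities$name[is.na(foc)], collapse = ", "))
  if (anyDuplicated(foc))
    stop("localities map to the same cell: ",
         paste(localities$name[duplicated(foc) | duplicated(foc, fromLast = TRUE)],
               collapse = ", "))
  names(foc) <- localities$name

  # connected components by union-find with path halving
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }
    a
  }
  for (k in seq_along(ei)) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))

  structure(list(n_nodes = n, edges_i = ei, edges_j = ej, diagonal = dg,
                 node_id = node_id, focal = foc, comp = comp,
                 cell_size = resistance$cell_size, origin = resistance$origin,
                 nodata = resistance$nodata, edge_res = NULL),
            class = "grid_graph")
}

#' @rdname build_grid_graph
#' @param template a `grid_graph` from [graph_template()].
#' @export
graph_set_resistance <- function(template, resistance) {
  r <- resistance$values[!is.na(resistance$values)]
  if (any(r <= 0)) stop("cell resistances must be > 0")
  er <- (r[template$edges_i] + r[template$edges_j]) / 2
  er[template$diagonal] <- er[template$diagonal] * sqrt(2)
  template$edge_res <- er
  template
}

#' @export
print.grid_graph <- function(x, ...) {
  cat(sprintf("<grid_graph> %d nodes, %d edges, %d focal nodes, %d component(s)\n",
              x$n_nodes, length(x$edges_i), length(x$focal), max(x$comp)))
  invisible(x)
}

# sparse graph Laplacian from conductances
.graph_laplacian <- function(graph) {
  cond <- 1 / graph$edge_res
  n <- graph$n_nodes
  deg <- numeric(n)
  tab <- rowsum(c(cond, cond), c(graph$edges_i, graph$edges_j))
  deg[as.integer(rownames(tab))] <- tab[, 1]
  Matrix::sparseMatrix(
    i = c(graph$edges_i, graph$edges_j, seq_len(n)),
    j = c(graph$edges_j, graph$edges_i, seq_len(n)),
    x = c(-cond, -cond, deg), dims = c(n, n))
}

# For one component: ground one focal node g, factorize the reduced
# Laplacian once, and return the k x k matrix S over the component's focal
# nodes f (S[g,] = 0 row/col) with S[i,j] = e_i' L_g^{-1} e_j, plus the full
# potential columns needed for current maps.
.solve_component <- function(graph, L, focal_nodes, want_potentials = FALSE) {
  g <- focal_nodes[1]
  keep <- setdiff(which(graph$comp == graph$comp[g]), g)
  Lg <- L[keep, keep, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lg), LDL = FALSE, perm = TRUE)
  others <- focal_nodes[-1]
  k <- length(focal_nodes)
  pos <- match(others, keep)
  E <- Matrix::sparseMatrix(i = pos, j = seq_along(pos), x = 1,
                            dims = c(length(keep), max(1L, length(pos))))
  X <- as.matrix(Matrix::solve(ch, E))
  S <- matrix(0, k, k)
  if (length(others)) S[-1, -1] <- X[pos, , drop = FALSE]
  V <- NULL
  if (want_potentials) {
    V <- matrix(0, graph$n_nodes, k)      # potentials with ground at g
    if (length(others)) V[keep, -1] <- X
  }
  list(S = S, V = V, ground = g)
}

#' Two-point effective resistance
#'
#' Grounds one focal node, injects unit current at the other, solves the
#' reduced graph-Laplacian system and reads off the potential difference.
#'
#' @param graph a `grid_graph`.
#' @param a,b locality names (or focal indices).
#' @return effective resistance; `Inf` if the pair is disconnected.
#' @export
effective_resistance <- function(graph, a, b) {
  foc <- .resolve_focal(graph, c(a, b))
  if (foc[1] == foc[2]) stop("focal nodes must differ")
  if (graph$comp[foc[1]] != graph$comp[foc[2]]) return(Inf)
  L <- .graph_laplacian(graph)
  sol <- .solve_component(graph, L, foc)
  sol$S[2, 2]                                   # ground = a, so R = S_bb
}

.resolve_focal <- function(graph, which) {
  if (is.character(which)) {
    miss <- setdiff(which, names(graph$focal))
    if (length(miss)) stop("unknown localities: ", paste(miss, collapse = ", "))
    unname(graph$focal[which])
  } else unname(graph$focal[which])
}

#' Pairwise effective-resistance matrix over all focal nodes
#'
#' One sparse Cholesky factorization per connected component is reused for
#' every pair in it. Pairs spanning components get `Inf`.
#'
#' @param graph a `grid_graph`.
#' @return a `pairwise_matrix` of kind `"resistance"`.
#' @export
resistance_matrix <- function(graph) {
  nms <- names(graph$focal)
  k <- length(graph$focal)
  if (k < 2L) stop("need >= 2 focal nodes")
  out <- matrix(Inf, k, k, dimnames = list(nms, nms))
  diag(out) <- 0
  L <- .graph_laplacian(graph)
  for (cp in unique(graph$comp[graph$focal])) {
    in_cp <- which(graph$comp[graph$focal] == cp)
    if (length(in_cp) < 2L) next
    sol <- .solve_component(graph, L, unname(graph$focal[in_cp]))
    S <- sol$S
    d <- diag(S)
    R <- outer(d, d, "+") - 2 * S
    out[in_cp, in_cp] <- R
  }
  pairwise_matrix(out, kind = "resistance")
}

#' Cumulative current map over all focal pairs
#'
#' For every unordered focal pair, a unit current is injected at one node and
#' extracted at the other; the per-node current is half the sum of absolute
#' currents on incident edges, except at the source and sink where it is the
#' injected unit. The cumulative map sums over all pairs and is written back
#' onto the grid (high current = likely movement corridor).
#'
#' @param graph a `grid_graph`.
#' @return `land_grid` of cumulative current.
#' @export
current_map <- function(graph) {
  k <- length(graph$focal)
  if (k < 2L) stop("need >= 2 focal nodes")
  if (length(unique(graph$comp[graph$focal])) > 1L)
    stop("focal nodes span disconnected components; current map undefined")
  L <- .graph_laplacian(graph)
  sol <- .solve_component(graph, L, unname(graph$focal), want_potentials = TRUE)
  V <- sol$V
  cond <- 1 / graph$edge_res
  nE <- length(graph$edges_i)
  absB <- Matrix::sparseMatrix(
    i = c(graph$edges_i, graph$edges_j), j = rep(seq_len(nE), 2), x = 0.5,
    dims = c(graph$n_nodes, nE))
  cum <- numeric(graph$n_nodes)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    v <- V[, i] - V[, j]
    I <- abs(v[graph$edges_i] - v[graph$edges_j]) * cond
    nodecur <- as.numeric(absB %*% I)
    nodecur[graph$focal[c(i, j)]] <- 1
    cum <- cum + nodecur
  }
  out <- matrix(NA_real_, nrow(graph$node_id), ncol(graph$node_id))
  out[!is.na(graph$node_id)] <- cum[graph$node_id[!is.na(graph$node_id)]]
  land_grid(out, graph$cell_size, graph$origin, graph$nodata)
}
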