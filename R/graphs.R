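# Network container and generators.
#
# All dynamics in the package run on simple, undirected, connected graphs
# with 0-based contiguous node ids.  The container keeps the adjacency as a
# sparse 0/1 Matrix plus an environment used to cache operators and spectra.

#' Construct a network from an adjacency matrix
#'
#' @param adjacency square symmetric 0/1 matrix (dense or sparse) with zero
#'   diagonal.
#' @param name short label used in printing.
#' @param check verify symmetry, binary entries, zero diagonal and
#'   connectivity (warning only for the latter).
#' @return an object of class `shnet`: list with `n` (node count),
#'   `adjacency` (sparse pattern-symmetric `dgCMatrix`) and a cache
#'   environment.  Node ids are `0:(n-1)` and index rows/columns of
#'   `adjacency` shifted by one.
#' @export
as_network <- function(adjacency, name = "network", check = TRUE) {
  A <- methods::as(methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  if (check) {
    if (ncol(A) != n) stop("adjacency must be square", call. = FALSE)
    if (!Matrix::isSymmetric(A)) stop("adjacency must be symmetric", call. = FALSE)
    if (any(Matrix::diag(A) != 0)) stop("adjacency must have zero diagonal", call. = FALSE)
    x <- A@x
    if (length(x) && !all(x %in% c(0, 1)))
      stop("adjacency entries must be 0 or 1", call. = FALSE)
    if (n > 1 && !network_is_connected(A))
      warning("network is not connected; dynamics assume a single component",
              call. = FALSE)
  }
  structure(list(n = n, adjacency = Matrix::drop0(A), name = name,
                 cache = new.env(parent = emptyenv())),
            class = "shnet")
}

# connectivity check by sparse BFS/level expansion
network_is_connected <- function(A) {
  n <- nrow(A)
  if (n <= 1) return(TRUE)
  reached <- logical(n)
  reached[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    sub <- methods::as(A[frontier, , drop = FALSE], "TsparseMatrix")
    nb <- unique(sub@j + 1L)
    nb <- nb[!reached[nb]]
    reached[nb] <- TRUE
    frontier <- nb
  }
  all(reached)
}

#' @export
print.shnet <- function(x, ...) {
  e <- Matrix::nnzero(x$adjacency) / 2
  cat(sprintf("<shnet> %s: %d nodes, %d edges, mean degree %.3g\n",
              x$name, x$n, e, 2 * e / x$n))
  invisible(x)
}

#' Number of edges of a network
#' @param net an `shnet` object.
#' @return integer edge count.
#' @export
edge_count <- function(net) as.integer(Matrix::nnzero(net$adjacency) / 2)

#' Node degrees
#' @param net an `shnet` object.
#' @return integer vector of degrees, one per node.
#' @export
degrees <- function(net) as.integer(Matrix::rowSums(net$adjacency))

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

shnet_from_igraph <- function(g, name) {
  A <- igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  A@x[] <- 1
  as_network(A, name = name, check = FALSE)
}

#' Barabasi-Albert scale-free network
#'
#' Preferential-attachment growth: the seed is a single edge for `m = 1` and
#' a clique on `m + 1` nodes for `m > 1`; every subsequent node attaches with
#' `m` preferential draws without replacement, so the graph is simple and
#' connected by construction.  `m = 1` yields a tree.
#'
#' @param n number of nodes (`n > m`).
#' @param m edges added per new node (`m >= 1`).
#' @param seed integer RNG seed; the same `(n, m, seed)` always returns the
#'   identical edge set.
#' @return an `shnet` network.
#' @export
generate_ba <- function(n, m = 1, seed = 1) {
  if (!is.numeric(n) || !is.numeric(m) || n <= m || m < 1)
    stop("invalid parameters: need n > m >= 1", call. = FALSE)
  start <- if (m == 1) igraph::make_graph(c(1, 2), directed = FALSE)
           else igraph::make_full_graph(m + 1)
  g <- with_seed(seed, igraph::sample_pa(
    n, power = 1, m = m, directed = FALSE,
    algorithm = "psumtree", start.graph = start))
  net <- shnet_from_igraph(g, sprintf("BA(n=%d, m=%d, seed=%d)", n, m, seed))
  stopifnot(network_is_connected(net$adjacency))
  net
}

#' Erdos-Renyi random network (giant component)
#'
#' Draws `G(n, p)` with `p = mean_degree / (n - 1)`.  If the draw is
#' disconnected, the giant component is kept and relabelled to contiguous
#' 0-based ids; the reduction is reported with a message and the surviving
#' original ids are kept in the `original_ids` attribute.
#'
#' @param n number of nodes before any reduction.
#' @param mean_degree target mean degree, `0 < mean_degree < n - 1`.
#' @param seed integer RNG seed.
#' @return an `shnet` network with `node_count <= n`.
#' @export
generate_er <- function(n, mean_degree, seed = 1) {
  if (!is.numeric(mean_degree) || mean_degree <= 0 || mean_degree > n - 1)
    stop("invalid parameters: need 0 < mean_degree <= n - 1", call. = FALSE)
  p <- mean_degree / (n - 1)
  g <- with_seed(seed, igraph::sample_gnp(n, p, directed = FALSE))
  comp <- igraph::components(g)
  keep <- NULL
  if (comp$no > 1) {
    giant <- which.max(comp$csize)
    keep <- which(comp$membership == giant)
    g <- igraph::induced_subgraph(g, keep)
    message(sprintf("generate_er: graph disconnected; keeping giant component (%d of %d nodes)",
                    length(keep), n))
  }
  net <- shnet_from_igraph(g, sprintf("ER(n=%d, <k>=%g, seed=%d)", n, mean_degree, seed))
  if (!is.null(keep)) attr(net, "original_ids") <- keep - 1L
  net
}

#' Read a network from a whitespace-separated edge list
#'
#' One `i j` pair per line, 0-based integer ids, `#` comments allowed.
#' Duplicate and reversed pairs collapse to a single undirected edge.
#' Non-contiguous ids are relabelled to `0:(n-1)`; the original ids are
#' returned in the `original_ids` attribute (sidecar written by
#' [write_edge_list()] users if needed).
#'
#' @param path file path.
#' @return an `shnet` network (a warning is raised if it is disconnected).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("malformed-input: no edges in ", path, call. = FALSE)
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(toks, length, 1L) != 2L
  if (any(bad)) stop("malformed-input: expected two tokens per line", call. = FALSE)
  flat <- unlist(toks)
  if (any(!grepl("^[0-9]+$", flat)))
    stop("malformed-input: non-integer node id", call. = FALSE)
  ij <- matrix(as.integer(flat), ncol = 2, byrow = TRUE)
  if (any(ij[, 1] == ij[, 2]))
    stop("malformed-input: self-loop", call. = FALSE)
  ids <- sort(unique(as.vector(ij)))
  idx <- match(ij, ids)
  dim(idx) <- dim(ij)
  n <- length(ids)
  i <- pmin(idx[, 1], idx[, 2]); j <- pmax(idx[, 1], idx[, 2])
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n),
                            use.last.ij = TRUE)
  net <- as_network(A, name = basename(path))
  attr(net, "original_ids") <- ids
  net
}

#' Write a network as an edge list
#'
#' @param net an `shnet` network.
#' @param path output file path.
#' @return `path`, invisibly.  Each undirected edge is written once as
#'   `i j` with `i < j`, 0-based.
#' @export
write_edge_list <- function(net, path) {
  A <- methods::as(Matrix::triu(net$adjacency), "TsparseMatrix")
  o <- order(A@i, A@j)
  writeLines(c(sprintf("# shnet edge list: %d nodes, %d edges", net$n, length(o)),
               paste(A@i[o], A@j[o])), path)
  invisible(path)
}

#' Read a network from a GraphML file
#' @param path GraphML file path.
#' @return an `shnet` network (simplified: loops/multi-edges dropped).
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  shnet_from_igraph(g, basename(path))
}

#' First- and second-order connectivity profile
#'
#' For every node: degree `k` (row sum of the adjacency), two-jump degree
#' `k2` (number of distinct nodes at shortest-path distance exactly 2) and
#' two-walk count `s = sum_j A_ij k_j` (walks of length 2, with
#' multiplicity).  On a tree `s = k + k2` for every node.
#'
#' @param net an `shnet` network.
#' @return a data.frame with columns `node`, `k`, `k2`, `s`.
#' @export
connectivity_profile <- function(net) {
  A <- net$adjacency
  k <- Matrix::rowSums(A)
  s <- as.vector(A %*% k)
  B <- A %*% A                 # (i,j) = number of 2-walks
  two <- (B > 0) & !(A > 0)    # reachable in exactly 2, not adjacent
  Matrix::diag(two) <- FALSE
  k2 <- Matrix::rowSums(two)
  data.frame(node = 0:(net$n - 1), k = as.integer(k),
             k2 = as.integer(k2), s = as.integer(s))
}

#' Write a connectivity profile table
#' @param net an `shnet` network.
#' @param path output path for a comma-separated `node,k,k2,s` table.
#' @return `path`, invisibly.
#' @export
write_connectivity_profile <- function(net, path) {
  utils::write.csv(connectivity_profile(net), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
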