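# Coupling operators: Laplacian L2 = A - diag(k), bi-Laplacian L4 = L2 %*% L2,
# and the full coupling 2*L2 + L4.  All three annihilate the constant vector
# (conservation) and share one orthonormal eigenbasis; eig(L4) = eig(L2)^2.
# Operators and the Laplacian eigendecomposition are cached per network.

cache_get <- function(net, key, compute) {
  if (!exists(key, envir = net$cache, inherits = FALSE))
    assign(key, compute(), envir = net$cache)
  get(key, envir = net$cache, inherits = FALSE)
}

#' Network Laplacian
#'
#' `L2 = A - diag(k)`: real, symmetric, negative semi-definite, rows sum to
#' zero.  This is the generator of diffusive (Fickian) exchange along links.
#'
#' @param net an `shnet` network.
#' @return sparse symmetric matrix with attribute `kind = "laplacian"`.
#' @export
laplacian <- function(net) {
  cache_get(net, "L2", function() {
    A <- net$adjacency
    L <- A - Matrix::Diagonal(net$n, Matrix::rowSums(A))
    structure(L, kind = "laplacian")
  })
}

#' Network bi-Laplacian
#'
#' The exact matrix square `L2 %*% L2`.  It couples nodes up to two jumps
#' apart, shares the Laplacian's eigenvectors, and its eigenvalues are the
#' squares of the Laplacian's.
#'
#' @param net an `shnet` network.
#' @return sparse symmetric matrix with attribute `kind = "bilaplacian"`.
#' @export
bilaplacian <- function(net) {
  cache_get(net, "L4", function() {
    L <- laplacian(net)
    structure(Matrix::drop0(L %*% L), kind = "bilaplacian")
  })
}

#' Full coupling operator
#'
#' `C = 2*L2 + L4`; the interaction current on a state `u` is `-C u`.
#' The combination produces short-range anti-correlation with nearest
#' neighbours and longer-range correlation with the two-jump neighbourhood.
#'
#' @param net an `shnet` network.
#' @return sparse symmetric matrix with attribute `kind = "coupling"`.
#' @export
coupling_matrix <- function(net) {
  cache_get(net, "C", function() {
    structure(Matrix::drop0(2 * laplacian(net) + bilaplacian(net)),
              kind = "coupling")
  })
}

#' Interaction current
#'
#' `I = -(2*L2 + L4) u`: the excitatory/inhibitory exchange felt by each
#' node.  Currents conserve the total state, `sum(I) = 0`, and vanish
#' identically on flat (constant) states.
#'
#' @param net an `shnet` network.
#' @param u nodal state vector of length `net$n`.
#' @return numeric vector of per-node currents.
#' @export
interaction_current <- function(net, u) {
  if (length(u) != net$n)
    stop("dimension-error: u has length ", length(u), ", expected ", net$n,
         call. = FALSE)
  -as.vector(coupling_matrix(net) %*% u)
}

#' Spectral decomposition of a symmetric operator
#'
#' Dense symmetric eigensolve, eigenvalues sorted in decreasing order.  For a
#' connected-network Laplacian the leading pair is the zero eigenvalue with
#' the uniform eigenvector.
#'
#' @param op symmetric matrix (e.g. from [laplacian()]).
#' @param count number of leading eigenpairs to return, or `"all"`.
#' @param values_only skip eigenvectors (faster).
#' @return list with `values` (decreasing) and `vectors` (orthonormal
#'   columns, `NULL` if `values_only`), class `shnet_spectrum`.
#' @export
operator_spectrum <- function(op, count = "all", values_only = FALSE) {
  M <- as.matrix(op)
  if (!isSymmetric(M, tol = 1e-8))
    stop("invalid-operator: matrix is not symmetric", call. = FALSE)
  e <- eigen(M, symmetric = TRUE, only.values = values_only)
  if (!identical(count, "all")) {
    count <- min(as.integer(count), nrow(M))
    e$values <- e$values[seq_len(count)]
    if (!values_only) e$vectors <- e$vectors[, seq_len(count), drop = FALSE]
  }
  structure(list(values = e$values,
                 vectors = if (values_only) NULL else e$vectors),
            class = "shnet_spectrum")
}

#' Laplacian spectrum of a network (cached)
#'
#' @param net an `shnet` network.
#' @param values_only drop eigenvectors.
#' @return an `shnet_spectrum` for the network Laplacian.
#' @export
network_spectrum <- function(net, values_only = FALSE) {
  key <- if (values_only) "spec_values" else "spec_full"
  if (!values_only && exists("spec_full", envir = net$cache, inherits = FALSE))
    return(get("spec_full", envir = net$cache))
  if (values_only && exists("spec_full", envir = net$cache, inherits = FALSE)) {
    full <- get("spec_full", envir = net$cache)
    return(structure(list(values = full$values, vectors = NULL),
                     class = "shnet_spectrum"))
  }
  cache_get(net, key, function() operator_spectrum(laplacian(net),
                                                   values_only = values_only))
}

#' @export
print.shnet_spectrum <- function(x, ...) {
  cat(sprintf("<shnet_spectrum> %d eigenvalues in [%.4g, %.4g]%s\n",
              length(x$values), min(x$values), max(x$values),
              if (is.null(x$vectors)) " (values only)" else ""))
  invisible(x)
}

#' Export an operator in coordinate triplet format
#'
#' @param op matrix (sparse or dense).
#' @param path output path; rows are `row col value`, 0-based, one nonzero
#'   per line.
#' @return `path`, invisibly.
#' @export
write_operator_triplets <- function(op, path) {
  T <- methods::as(Matrix::Matrix(op, sparse = TRUE), "TsparseMatrix")
  o <- order(T@i, T@j)
  writeLines(c("# row col value (0-based)",
               sprintf("%d %d %.17g", T@i[o], T@j[o], T@x[o])), path)
  invisible(path)
}
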