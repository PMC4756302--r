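# Small hand-checkable graphs used across the suite.

path3 <- function() as_network(rbind(c(0, 1, 0),
                                     c(1, 0, 1),
                                     c(0, 1, 0)), name = "P3")

star4 <- function() { # center = node 0, three leaves
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- 1; A[2:4, 1] <- 1
  as_network(A, name = "K1,3")
}

cycle_n <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- 1
  }
  as_network(A, name = sprintf("C%d", n))
}

complete_n <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  as_network(A, name = sprintf("K%d", n))
}

single_node <- function() as_network(matrix(0, 1, 1), name = "N1")

# ring Laplacian spectrum, circulant closed form
ring_spectrum <- function(n) sort(2 * (cos(2 * pi * (0:(n - 1)) / n) - 1),
                                  decreasing = TRUE)
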