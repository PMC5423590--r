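# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no data files.

random_network <- function(n, p = 0.4, directed = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (directed) {
    A <- matrix(stats::rbinom(n * n, 1L, p), n, n)
  } else {
    A <- matrix(0L, n, n)
    up <- upper.tri(A)
    A[up] <- stats::rbinom(sum(up), 1L, p)
    A <- A + t(A)
  }
  diag(A) <- 0L
  binary_network(A, directed = directed)
}

random_partition <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    p <- stats::runif(n) < 0.5
    if (sum(p) >= 1L && sum(!p) >= 1L) return(cp_partition(p))
  }
}

# independent violation counter: explicit loop over ordered pairs
brute_violations <- function(net, part) {
  core <- which(unclass(part))
  peri <- which(!unclass(part))
  vC <- 0L
  vP <- 0L
  for (i in core) for (j in core) if (i != j) vC <- vC + 1L - net$ties[i, j]
  for (i in peri) for (j in peri) if (i != j) vP <- vP + net$ties[i, j]
  list(v_core = vC, v_periphery = vP)
}

# a 20-actor directed network realizing the published social-work-journal
# solution counts: 6-actor core with 2 intra-core violations, 14-actor
# periphery with 8 intra-periphery violations, random inter-block ties.
# Synthetic stand-in for the co-citation matrix (not the published data);
# the criterion value depends only on the counts.
worked_example_network <- function(seed = 1) {
  set.seed(seed)
  n <- 20L
  core <- 1:6
  peri <- 7:20
  A <- matrix(0L, n, n)
  A[core, core] <- 1L
  core_pairs <- which(row(A) != col(A) &
                      row(A) %in% core & col(A) %in% core)
  A[sample(core_pairs, 2L)] <- 0L
  peri_pairs <- which(row(A) != col(A) &
                      row(A) %in% peri & col(A) %in% peri)
  A[sample(peri_pairs, 8L)] <- 1L
  inter <- which(xor(row(A) %in% core, col(A) %in% core))
  A[inter] <- as.integer(stats::runif(length(inter)) < 0.5)
  diag(A) <- 0L
  list(network = binary_network(A),
       partition = cp_partition(seq_len(n) %in% core))
}

# a network with a perfect core/periphery structure: complete core block,
# empty periphery block, arbitrary inter-block ties
perfect_structure_network <- function(n, n_core, p_between = 0.5,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  core <- seq_len(n) <= n_core
  A <- matrix(0L, n, n)
  A[core, core] <- 1L
  inter <- which(xor(row(A) <= n_core, col(A) <= n_core))
  A[inter] <- as.integer(stats::runif(length(inter)) < p_between)
  diag(A) <- 0L
  list(network = binary_network(A), partition = cp_partition(core))
}
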