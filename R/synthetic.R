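#' Generate a planted core/periphery network
#'
#' Draws a binary network with a known ("planted") core/periphery
#' partition: the first `round(core_fraction * n)` actors form the core,
#' and each off-diagonal pair receives a tie independently with the
#' density of its block — `p_core` within the core, `p_periphery` within
#' the periphery, and `p_between` for core–periphery pairs in either
#' direction. In undirected mode one Bernoulli draw per unordered pair is
#' mirrored. Core size is rounded half-up.
#'
#' Inter-block ties never enter the structure vectors, but their density
#' still shapes the search landscape (which alternative partitions score
#' well), which is why it is a design parameter. With
#' `p_core = p_periphery = p_between` the network is Erdős–Rényi and the
#' planted labels carry no signal.
#'
#' The benchmark design this generator emulates crosses
#' \eqn{n \in \{500, 1000, 2000\}}, core fractions \{.05, .10, .20\},
#' intra-core densities \{.70, .80\}, intra-periphery densities
#' \{.20, .30\} and inter-block densities \{.40, .60\}; see
#' [benchmark_design()].
#'
#' @param n number of actors.
#' @param core_fraction fraction of actors planted in the core, in (0, 1);
#'   both blocks must round to at least 2 actors.
#' @param p_core,p_periphery,p_between block tie probabilities in \[0, 1\].
#' @param directed logical; default `TRUE`.
#' @param seed optional integer seed (uses R's RNG).
#' @return list with `network` (a [binary_network()]) and `partition`
#'   (the planted [cp_partition()]).
#' @examples
#' pl <- generate_planted_network(100, 0.1, 0.8, 0.2, 0.5, seed = 42)
#' build_state(pl$network, pl$partition)
#' @export
generate_planted_network <- function(n, core_fraction, p_core, p_periphery,
                                     p_between, directed = TRUE,
                                     seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 4)
    stop("n must be at least 4")
  n <- as.integer(n)
  if (!is.numeric(core_fraction) || core_fraction <= 0 || core_fraction >= 1)
    stop("core_fraction must be in (0, 1)")
  probs <- c(p_core, p_periphery, p_between)
  if (!is.numeric(probs) || anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("block probabilities must lie in [0, 1]")
  nC <- as.integer(floor(core_fraction * n + 0.5))  # round half-up
  if (nC < 2L || n - nC < 2L)
    stop("core_fraction * n must leave at least 2 actors in each block")
  if (!is.null(seed)) set.seed(seed)

  core <- c(rep(TRUE, nC), rep(FALSE, n - nC))
  P <- matrix(p_between, n, n)
  P[core, core] <- p_core
  P[!core, !core] <- p_periphery
  if (directed) {
    A <- matrix(as.integer(stats::runif(n * n) < P), n, n)
  } else {
    A <- matrix(0L, n, n)
    upper <- upper.tri(A)
    A[upper] <- as.integer(stats::runif(sum(upper)) < P[upper])
    A <- A + t(A)
  }
  diag(A) <- 0L
  list(network = binary_network(A, directed = directed),
       partition = cp_partition(core))
}

#' The full crossed benchmark design
#'
#' One row per cell of the crossed design: actor counts, core fractions,
#' and the three block densities, with `replicates` problems per cell.
#' Defaults give the full 3 x 3 x 2 x 2 x 2 = 72-cell design; pass subsets
#' for a scaled-down run. Seeds are assigned deterministically from
#' `base_seed` so the same design frame always yields the same problems.
#'
#' @param n actor counts (default `c(500, 1000, 2000)`).
#' @param core_fraction core fractions (default `c(.05, .10, .20)`).
#' @param p_core intra-core densities (default `c(.70, .80)`).
#' @param p_periphery intra-periphery densities (default `c(.20, .30)`).
#' @param p_between inter-block densities (default `c(.40, .60)`).
#' @param replicates problems per cell (default 3).
#' @param base_seed seed offset for problem generation.
#' @return data.frame with one row per test problem: `problem`, the five
#'   design columns, `replicate` and `seed`.
#' @export
benchmark_design <- function(n = c(500, 1000, 2000),
                             core_fraction = c(.05, .10, .20),
                             p_core = c(.70, .80),
                             p_periphery = c(.20, .30),
                             p_between = c(.40, .60),
                             replicates = 1L, base_seed = 1L) {
  g <- expand.grid(replicate = seq_len(replicates), p_between = p_between,
                   p_periphery = p_periphery, p_core = p_core,
                   core_fraction = core_fraction, n = n,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("n", "core_fraction", "p_core", "p_periphery", "p_between",
             "replicate")]
  g$problem <- seq_len(nrow(g))
  g$seed <- base_seed + g$problem
  g[, c("problem", "n", "core_fraction", "p_core", "p_periphery",
        "p_between", "replicate", "seed")]
}
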