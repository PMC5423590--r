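#' Explicit ideal and observed structure vectors
#'
#' The slow, direct route to the criterion: materialize the ideal vector
#' \eqn{x(\pi)} (a 1 for each of the \eqn{d_C} ordered intra-core dyads,
#' then a 0 for each of the \eqn{d_P} intra-periphery dyads) and the
#' observed vector \eqn{y(\pi)} (the tie values \eqn{a_{ij}} over the same
#' dyads, in the same order). Inter-block dyads never enter either vector.
#'
#' Dyads are enumerated row-major within each block — for each block member
#' \eqn{i} in index order, all \eqn{j \ne i} in index order — a fixed order
#' that the correlation does not depend on but deterministic tests do.
#'
#' This construction exists as an independent check on the constant-based
#' evaluation in [correlation_from_state()]; it is linear in \eqn{d} and
#' not meant for use inside search loops.
#'
#' @param net a [binary_network()].
#' @param part a [cp_partition()].
#' @return list with binary vectors `ideal` and `observed`, both of length
#'   \eqn{d = d_C + d_P}.
#' @seealso [pearson_oracle()]
#' @export
build_structure_vectors <- function(net, part) {
  part <- check_partition(net, part)
  core <- which(unclass(part))
  peri <- which(!unclass(part))
  block_values <- function(members) {
    k <- length(members)
    if (k < 2L) return(integer(0))
    m <- net$ties[members, members, drop = FALSE]
    as.integer(t(m))[as.vector(t(row(m) != col(m)))]  # row-major, skip diag
  }
  y_core <- block_values(core)
  y_peri <- block_values(peri)
  if (length(y_core) + length(y_peri) == 0L)
    stop("both blocks are smaller than 2 actors; no intra-block dyads exist")
  list(ideal = c(rep(1L, length(y_core)), rep(0L, length(y_peri))),
       observed = c(y_core, y_peri))
}

#' Textbook Pearson correlation of the structure vectors
#'
#' Reference implementation of the criterion: the sample Pearson
#' correlation of `ideal` and `observed` under the population
#' (divide-by-\eqn{d}) variance convention — the convention under which the
#' intermediate variance and covariance terms match the closed-form
#' constants (the correlation itself is convention-invariant).
#'
#' @param vectors list with `ideal` and `observed`, as returned by
#'   [build_structure_vectors()].
#' @return correlation in \[-1, 1\], or `NA_real_` if either vector is
#'   constant.
#' @export
pearson_oracle <- function(vectors) {
  x <- as.numeric(vectors$ideal)
  y <- as.numeric(vectors$observed)
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  d <- length(x)
  sxy <- mean(x * y) - mean(x) * mean(y)
  s2x <- mean(x^2) - mean(x)^2
  s2y <- mean(y^2) - mean(y)^2
  sxy / sqrt(s2x * s2y)
}

#' Exhaustive search over all core/periphery partitions
#'
#' Enumerates all \eqn{2^n} assignments of actors to core/periphery, skips
#' those whose correlation is undefined, and returns the maximum
#' correlation with one argmax partition (ties broken towards the
#' lexicographically smallest membership vector, periphery sorting before
#' core). Cost is \eqn{O(2^n n^2)}, so a hard guard rejects `n > 20`;
#' use [anneal()] beyond that.
#'
#' @param net a [binary_network()] with at most 20 actors.
#' @return list with `partition` (a [cp_partition()] or `NULL`) and `r`
#'   (`NA_real_` when every partition is undefined, as happens for
#'   \eqn{n < 4} or complete/empty networks).
#' @export
exhaustive_optimum <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- net$n
  if (n > 20L)
    stop("exhaustive enumeration is limited to n <= 20 (2^n partitions); ",
         "use anneal() for larger networks")
  A <- net$ties
  best_r <- NA_real_
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    core <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))))
    nC <- sum(core)
    if (nC < 2L || n - nC < 2L) next  # s_X^2 = 0: undefined
    st <- build_state(net, cp_partition(core))
    r <- correlation_from_state(st)
    if (!is.na(r) && (is.na(best_r) || r > best_r)) {
      best_r <- r
      best <- core
    }
  }
  list(partition = if (is.null(best)) NULL else cp_partition(best),
       r = best_r)
}
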