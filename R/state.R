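#' Dyad counts for a core/periphery split
#'
#' A block of \eqn{k} actors contains \eqn{k^2 - k} ordered dyads (ordered
#' pairs of distinct actors). These counts, together with the violation
#' counts, are all that is needed to evaluate the correlation criterion.
#'
#' @param n_core,n_periphery non-negative block sizes with
#'   `n_core + n_periphery >= 2`.
#' @return list with integer elements `d_core` (\eqn{d_C = n_C^2 - n_C}),
#'   `d_periphery` (\eqn{d_P = n_P^2 - n_P}) and `d` (their sum).
#' @examples
#' dyad_counts(6, 14)  # d_core 30, d_periphery 182, d 212
#' @export
dyad_counts <- function(n_core, n_periphery) {
  if (!is.numeric(n_core) || !is.numeric(n_periphery) ||
      length(n_core) != 1L || length(n_periphery) != 1L ||
      is.na(n_core) || is.na(n_periphery) ||
      n_core < 0 || n_periphery < 0 ||
      n_core != round(n_core) || n_periphery != round(n_periphery))
    stop("block sizes must be non-negative integers")
  if (n_core + n_periphery < 2)
    stop("need at least 2 actors in total")
  nC <- as.integer(n_core)
  nP <- as.integer(n_periphery)
  if (is.na(nC) || is.na(nP))
    stop("block sizes too large for integer dyad counts")
  dC <- nC * nC - nC   # exact integer arithmetic throughout the counts
  dP <- nP * nP - nP
  list(d_core = dC, d_periphery = dP, d = dC + dP)
}

#' Count intra-block violations
#'
#' An intra-core violation is a 0 in the core block (a missing tie between
#' two core actors); an intra-periphery violation is a 1 in the periphery
#' block. Both counts run over ordered pairs of distinct actors, so in an
#' undirected network each absent/present edge contributes twice. The
#' diagonal is never read.
#'
#' @param net a [binary_network()].
#' @param part a [cp_partition()] covering all actors of `net`.
#' @return list with integer elements `v_core` and `v_periphery`.
#' @export
count_violations <- function(net, part) {
  part <- check_partition(net, part)
  core <- which(unclass(part))
  peri <- which(!unclass(part))
  nC <- length(core)
  nP <- length(peri)
  vC <- if (nC >= 2L) (nC^2 - nC) - sum(net$ties[core, core]) else 0L
  vP <- if (nP >= 2L) sum(net$ties[peri, peri]) else 0L
  list(v_core = as.integer(vC), v_periphery = as.integer(vP))
}

#' Partition state: the constants behind the correlation criterion
#'
#' For a partition \eqn{\pi} of a binary network into core and periphery,
#' the correlation between the ideal and observed structure vectors is a
#' closed-form function of seven integers: the block sizes \eqn{n_C, n_P},
#' the dyad counts \eqn{d_C, d_P, d} and the violation counts
#' \eqn{v_C, v_P}. `build_state()` computes them from scratch;
#' [evaluate_move()] updates them incrementally in \eqn{O(n)}.
#'
#' `cp_state()` assembles a state directly from the counts, which is useful
#' for evaluating the criterion for a published solution without the tie
#' matrix at hand.
#'
#' @param net a [binary_network()].
#' @param part a [cp_partition()].
#' @return An object of class `cp_state`: a list with integer fields
#'   `n_core`, `n_periphery`, `d_core`, `d_periphery`, `d`, `v_core`,
#'   `v_periphery`.
#' @examples
#' st <- cp_state(n_core = 6, n_periphery = 14, v_core = 2, v_periphery = 8)
#' correlation_from_state(st)  # 0.82561
#' @export
build_state <- function(net, part) {
  part <- check_partition(net, part)
  v <- count_violations(net, part)
  cp_state(core_size(part), periphery_size(part), v$v_core, v$v_periphery)
}

#' @rdname build_state
#' @param n_core,n_periphery block sizes.
#' @param v_core,v_periphery violation counts; must satisfy
#'   \eqn{0 \le v_C \le d_C} and \eqn{0 \le v_P \le d_P}.
#' @export
cp_state <- function(n_core, n_periphery, v_core, v_periphery) {
  dy <- dyad_counts(n_core, n_periphery)
  v_core <- as.integer(v_core)
  v_periphery <- as.integer(v_periphery)
  if (is.na(v_core) || v_core < 0L || v_core > dy$d_core)
    stop("v_core must lie in [0, d_core]")
  if (is.na(v_periphery) || v_periphery < 0L || v_periphery > dy$d_periphery)
    stop("v_periphery must lie in [0, d_periphery]")
  structure(list(n_core = as.integer(n_core),
                 n_periphery = as.integer(n_periphery),
                 d_core = dy$d_core, d_periphery = dy$d_periphery, d = dy$d,
                 v_core = v_core, v_periphery = v_periphery),
            class = "cp_state")
}

#' @export
print.cp_state <- function(x, ...) {
  cat(sprintf(
    "cp_state: n_C=%d n_P=%d d_C=%d d_P=%d d=%d v_C=%d v_P=%d  r=%s\n",
    x$n_core, x$n_periphery, x$d_core, x$d_periphery, x$d,
    x$v_core, x$v_periphery,
    {
      r <- correlation_from_state(x)
      if (is.na(r)) "undefined" else sprintf("%.5f", r)
    }))
  invisible(x)
}

#' Correlation criterion from a partition state
#'
#' Evaluates the Pearson correlation \eqn{r_{XY}(\pi)} between the ideal
#' structure vector \eqn{x(\pi)} (ones over intra-core dyads, zeros over
#' intra-periphery dyads) and the observed vector \eqn{y(\pi)} (the tie
#' values over the same dyads) in closed form from the state constants:
#' \deqn{s_X^2 = (d_C/d)(d_P/d),}
#' \deqn{s_Y^2 = ((d_C - v_C + v_P)/d)\,((d_P - v_P + v_C)/d),}
#' \deqn{s_{XY} = (d_C - v_C)/d - (d_C/d)((d_C - v_C + v_P)/d),}
#' \deqn{r_{XY} = s_{XY} / \sqrt{s_X^2\, s_Y^2}.}
#' Variances follow the population (divide-by-\eqn{d}) convention.
#'
#' The correlation is undefined when either vector is constant: a degenerate
#' partition (\eqn{n_C \le 1} or \eqn{n_P \le 1}, so \eqn{s_X^2 = 0}) or a
#' constant observed vector (\eqn{s_Y^2 = 0}, e.g. a complete or empty
#' network). `correlation_from_state()` then returns `NA_real_`;
#' `correlation_components()` reports the intermediates with `r = NA`.
#'
#' @param state a [cp_state()].
#' @return `correlation_from_state()`: the correlation in \[-1, 1\], or
#'   `NA_real_` when undefined. `correlation_components()`: list with
#'   `s2_ideal` (\eqn{s_X^2}), `s2_observed` (\eqn{s_Y^2}), `covariance`
#'   (\eqn{s_{XY}}) and `r`.
#' @examples
#' correlation_components(cp_state(6, 14, 2, 8))
#' @export
correlation_from_state <- function(state) {
  correlation_components(state)$r
}

#' @rdname correlation_from_state
#' @export
correlation_components <- function(state) {
  stopifnot(inherits(state, "cp_state"))
  d <- as.numeric(state$d)
  dC <- as.numeric(state$d_core)
  dP <- as.numeric(state$d_periphery)
  vC <- as.numeric(state$v_core)
  vP <- as.numeric(state$v_periphery)
  s2x <- (dC / d) * (dP / d)
  s2y <- ((dC - vC + vP) / d) * ((dP - vP + vC) / d)
  sxy <- (dC - vC) / d - (dC / d) * ((dC - vC + vP) / d)
  r <- if (s2x <= 0 || s2y <= 0) NA_real_ else sxy / sqrt(s2x * s2y)
  list(s2_ideal = s2x, s2_observed = s2y, covariance = sxy, r = r)
}

#' Evaluate a single-actor move incrementally
#'
#' Returns the [cp_state()] of the partition obtained from `part` by moving
#' actor `h` to the other block, without rebuilding the state from scratch.
#' Only the ties between `h` and the members of the block it leaves or
#' joins enter the update, so one evaluation costs \eqn{O(n)}:
#' moving `h` out of the core removes \eqn{\sum_{j \ne h \in T_1}
#' (1 - a_{hj}) + (1 - a_{jh})} from \eqn{v_C} and adds
#' \eqn{\sum_{j \ne h \in T_0} a_{hj} + a_{jh}} to \eqn{v_P}; moving `h`
#' into the core is the mirror image. All counts stay exact integers.
#'
#' The input `state` must be the state of `part`; it is not modified.
#'
#' @param state the [cp_state()] of `part`.
#' @param net a [binary_network()].
#' @param part the current [cp_partition()].
#' @param h index of the actor to flip.
#' @return the `cp_state` of `flip_actor(part, h)`.
#' @export
evaluate_move <- function(state, net, part, h) {
  stopifnot(inherits(state, "cp_state"))
  part <- check_partition(net, part)
  n <- net$n
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 1 || h > n)
    stop("`h` must be an actor index in 1..", n)
  h <- as.integer(h)
  core <- unclass(part)
  vC <- state$v_core
  vP <- state$v_periphery
  if (core[h]) {
    # core -> periphery: h leaves T1, joins T0 (h excluded from both sums)
    mates <- core; mates[h] <- FALSE
    others <- !core
    vC <- vC - sum((1L - net$ties[h, mates]) + (1L - net$ties[mates, h]))
    vP <- vP + sum(net$ties[h, others] + net$ties[others, h])
    cp_state(state$n_core - 1L, state$n_periphery + 1L, vC, vP)
  } else {
    # periphery -> core
    mates <- !core; mates[h] <- FALSE
    others <- core
    vP <- vP - sum(net$ties[h, mates] + net$ties[mates, h])
    vC <- vC + sum((1L - net$ties[h, others]) + (1L - net$ties[others, h]))
    cp_state(state$n_core + 1L, state$n_periphery - 1L, vC, vP)
  }
}
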