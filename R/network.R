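#' Construct a binary network
#'
#' A binary network is an \eqn{n \times n} 0/1 tie matrix \eqn{A = [a_{ij}]}
#' over \eqn{n \ge 2} actors, with \eqn{a_{ij} = 1} when there is a tie from
#' actor \eqn{i} to actor \eqn{j}. The main diagonal carries no information
#' and is never consulted by any operation in the package (it is stored as 0).
#'
#' @param ties square numeric/integer/logical matrix of ties; off-diagonal
#'   entries must be 0 or 1 (use [read_network()] to coerce weighted input).
#' @param directed logical; if `FALSE` the off-diagonal of `ties` must be
#'   symmetric (an asymmetric matrix is an error, never silently symmetrized).
#' @param labels character vector of unique actor labels, one per row of
#'   `ties`. Defaults to the rownames of `ties`, or `"a1" ... "an"`.
#' @return An object of class `binary_network`: a list with elements `n`,
#'   `ties` (integer matrix, zero diagonal), `directed`, and `labels`.
#' @examples
#' A <- matrix(0L, 4, 4); A[1, 2] <- A[2, 1] <- 1L
#' net <- binary_network(A, directed = FALSE)
#' net$n
#' @seealso [read_network()], [generate_planted_network()]
#' @export
binary_network <- function(ties, directed = TRUE, labels = NULL) {
  if (!is.matrix(ties) || nrow(ties) != ncol(ties))
    stop("`ties` must be a square matrix")
  n <- nrow(ties)
  if (n < 2L) stop("a binary network needs at least 2 actors")
  ties <- structure(as.integer(ties), dim = dim(ties))
  diag(ties) <- 0L
  off <- ties[row(ties) != col(ties)]
  if (anyNA(off) || any(off != 0L & off != 1L))
    stop("off-diagonal ties must be 0 or 1")
  if (!directed && !identical(ties, t(ties)))
    stop("`ties` is asymmetric but `directed = FALSE`; ",
         "symmetrize explicitly or read with directed = TRUE")
  if (is.null(labels)) labels <- rownames(ties)
  if (is.null(labels)) labels <- paste0("a", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("`labels` must be ", n, " unique strings")
  dimnames(ties) <- NULL
  structure(list(n = n, ties = ties, directed = directed, labels = labels),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  dens <- network_density(x)
  cat(sprintf("binary_network: %d actors, %s, density %.4f\n",
              x$n, if (x$directed) "directed" else "undirected", dens))
  invisible(x)
}

#' Density of a binary network
#'
#' Fraction of ordered off-diagonal pairs with a tie.
#'
#' @param net a [binary_network()].
#' @return numeric scalar in \[0, 1\].
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  sum(net$ties) / (net$n^2 - net$n)
}

#' Construct a core/periphery partition
#'
#' Assigns every actor to exactly one of the two blocks: the core
#' \eqn{T_1} or the periphery \eqn{T_0}.
#'
#' @param membership either a logical vector (`TRUE` = core) or a character
#'   vector of `"core"` / `"periphery"` labels (case-insensitive), one entry
#'   per actor.
#' @return An object of class `cp_partition`: a logical vector, `TRUE` for
#'   core members.
#' @examples
#' p <- cp_partition(c(TRUE, TRUE, FALSE, FALSE))
#' core_size(p)
#' @export
cp_partition <- function(membership) {
  if (is.character(membership) || is.factor(membership)) {
    m <- tolower(as.character(membership))
    if (!all(m %in% c("core", "periphery")))
      stop("character membership must be 'core' or 'periphery'")
    membership <- m == "core"
  }
  if (!is.logical(membership) || anyNA(membership))
    stop("membership must be logical (TRUE = core) or 'core'/'periphery'")
  structure(as.logical(membership), class = "cp_partition")
}

#' @export
print.cp_partition <- function(x, ...) {
  cat(sprintf("cp_partition: %d core, %d periphery\n",
              sum(x), sum(!x)))
  invisible(x)
}

#' @rdname cp_partition
#' @param part a `cp_partition`.
#' @return `core_size()` / `periphery_size()`: integer block sizes.
#' @export
core_size <- function(part) sum(unclass(part))

#' @rdname cp_partition
#' @export
periphery_size <- function(part) sum(!unclass(part))

#' Flip one actor between core and periphery
#'
#' The elementary neighbourhood move of the local search: actor `h` changes
#' block, everyone else stays put.
#'
#' @param part a [cp_partition()].
#' @param h actor index in `1:n`.
#' @return the modified `cp_partition`.
#' @export
flip_actor <- function(part, h) {
  n <- length(part)
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 1 || h > n)
    stop("`h` must be an actor index in 1..", n)
  part[[h]] <- !part[[h]]
  part
}

check_partition <- function(net, part) {
  stopifnot(inherits(net, "binary_network"))
  if (!inherits(part, "cp_partition"))
    part <- cp_partition(part)
  if (length(part) != net$n)
    stop("partition has ", length(part), " actors but network has ", net$n)
  part
}
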