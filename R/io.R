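#' Read a binary network from a file
#'
#' Supports three plain-text formats:
#' \describe{
#'   \item{dense}{square CSV/TSV 0/1 matrix; a header row and/or a label
#'     column are detected automatically; diagonal values are ignored.}
#'   \item{edgelist}{two whitespace- or tab-separated label columns, one
#'     edge per line; actors are the union of labels, sorted
#'     lexicographically; repeated edges are idempotent. Directed unless
#'     `directed = FALSE`, in which case edges are symmetrized by OR.}
#'   \item{pajek}{Pajek `.net` files via \pkg{igraph} (`*Vertices` with
#'     `*Arcs` directed and `*Edges` symmetric, 1-based numbering).}
#' }
#' Any nonzero numeric tie value is coerced to 1 with a warning. For dense
#' input with `directed = FALSE`, an asymmetric matrix is an error, never
#' silently symmetrized.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"dense"`, `"edgelist"`, `"pajek"`.
#'   `"auto"` uses the `.net` extension for Pajek, a leading `*` line for
#'   Pajek, two-column non-numeric content for edge lists, and square
#'   numeric content for dense matrices.
#' @param directed logical; for edge lists, `FALSE` symmetrizes; for dense
#'   input, `FALSE` requires symmetry. Ignored for Pajek (directedness
#'   comes from the file).
#' @return a [binary_network()].
#' @export
read_network <- function(path, format = c("auto", "dense", "edgelist",
                                          "pajek"),
                         directed = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- sniff_format(path)
  switch(format,
         dense = read_dense_network(path, directed),
         edgelist = read_edgelist_network(path, directed),
         pajek = read_pajek_network(path))
}

sniff_format <- function(path) {
  if (grepl("\\.net$", path, ignore.case = TRUE)) return("pajek")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("^\\s*\\*", first)) return("pajek")
  line1 <- scan(text = first, what = character(), quiet = TRUE,
                sep = if (grepl(",", first)) "," else "")
  if (length(line1) == 2L &&
      anyNA(suppressWarnings(as.numeric(line1))))
    return("edgelist")
  n_lines <- length(readLines(path, warn = FALSE))
  if (length(line1) == 2L && n_lines != 2L) return("edgelist")
  "dense"
}

read_dense_network <- function(path, directed = TRUE) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first)) "," else ""
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           strip.white = TRUE)
  labels <- NULL
  first_row_num <- !anyNA(suppressWarnings(as.numeric(unlist(raw[1, ]))))
  if (!first_row_num) {            # header row of labels
    hdr <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    labels <- hdr[(length(hdr) - nrow(raw) + 1):length(hdr)]
  }
  first_col_num <- !anyNA(suppressWarnings(as.numeric(raw[[1]])))
  if (!first_col_num) {            # label column
    labels <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
  }
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow(raw), ncol(raw)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric matrix entry at data row ", bad[1],
         ", column ", bad[2], " of ", path)
  }
  if (nrow(m) != ncol(m))
    stop("dense matrix in ", path, " is ", nrow(m), "x", ncol(m),
         "; it must be square")
  m <- coerce_binary(m, path)
  diag(m) <- 0L
  if (!directed && !identical(m, t(m)))
    stop("dense matrix in ", path, " is asymmetric but directed = FALSE")
  binary_network(m, directed = directed, labels = labels)
}

read_edgelist_network <- function(path, directed = TRUE) {
  e <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (ncol(e) < 2L)
    stop("edge list in ", path, " needs two label columns")
  e <- e[, 1:2]
  labels <- sort(unique(c(e[[1]], e[[2]])))
  n <- length(labels)
  if (n < 2L) stop("edge list in ", path, " has fewer than 2 actors")
  A <- matrix(0L, n, n)
  i <- match(e[[1]], labels)
  j <- match(e[[2]], labels)
  loops <- i == j
  A[cbind(i[!loops], j[!loops])] <- 1L   # repeated edges idempotent
  if (!directed) A <- pmax(A, t(A))      # symmetrize by OR
  binary_network(A, directed = directed, labels = labels)
}

read_pajek_network <- function(path) {
  g <- igraph::read_graph(path, format = "pajek")
  directed <- igraph::is_directed(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) labels <- igraph::vertex_attr(g, "id")
  A <- coerce_binary(A, path)
  diag(A) <- 0L
  binary_network(A, directed = directed, labels = labels)
}

coerce_binary <- function(m, path) {
  off <- m[row(m) != col(m)]
  if (any(off != 0 & off != 1)) {
    warning("nonzero tie values in ", path, " coerced to 1")
    m <- (m != 0) * 1
  }
  structure(as.integer(m), dim = dim(m))
}

#' Write a binary network to a file
#'
#' Inverse of [read_network()] for the same three formats. Dense output is
#' CSV with a label header row; edge-list output is TSV with one `from to`
#' pair per line (an undirected network writes each edge once); Pajek
#' output goes through \pkg{igraph}.
#'
#' @param net a [binary_network()].
#' @param path output file path.
#' @param format `"dense"`, `"edgelist"`, or `"pajek"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path,
                          format = c("dense", "edgelist", "pajek")) {
  stopifnot(inherits(net, "binary_network"))
  format <- match.arg(format)
  if (format == "dense") {
    m <- net$ties
    dimnames(m) <- list(NULL, net$labels)
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  } else if (format == "edgelist") {
    idx <- which(net$ties == 1L, arr.ind = TRUE)
    if (!net$directed) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    utils::write.table(
      data.frame(from = net$labels[idx[, 1]], to = net$labels[idx[, 2]]),
      path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    mode <- if (net$directed) "directed" else "undirected"
    g <- igraph::graph_from_adjacency_matrix(net$ties, mode = mode)
    g <- igraph::set_vertex_attr(g, "name", value = net$labels)
    igraph::write_graph(g, path, format = "pajek")
  }
  invisible(path)
}

#' Write / read a core/periphery partition
#'
#' The partition file is a two-column TSV — actor label, then `CORE` or
#' `PERIPHERY` — in the input label order.
#'
#' @param part a [cp_partition()].
#' @param labels actor labels in partition order.
#' @param path file path.
#' @return `write_partition()`: `path` invisibly; `read_partition()`: list
#'   with `labels` and `partition`.
#' @export
write_partition <- function(part, labels, path) {
  if (!inherits(part, "cp_partition")) part <- cp_partition(part)
  labels <- as.character(labels)
  if (length(labels) != length(part))
    stop("need one label per actor")
  utils::write.table(
    data.frame(actor = labels,
               block = ifelse(unclass(part), "CORE", "PERIPHERY")),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 2L)
    stop("partition file ", path, " must have two tab-separated columns")
  if (!all(tab[[2]] %in% c("CORE", "PERIPHERY")))
    stop("second column of ", path, " must be CORE or PERIPHERY")
  list(labels = tab[[1]], partition = cp_partition(tab[[2]] == "CORE"))
}

#' Write a JSON run report
#'
#' Serializes a [multi_restart()] run — network summary, configuration,
#' per-restart correlations, attraction rate, best partition and timing —
#' so a result can be reloaded and its correlation re-verified.
#'
#' @param net the analyzed [binary_network()].
#' @param result the list returned by [multi_restart()].
#' @param xi,tau1,seed the configuration used.
#' @param path output path for the JSON report.
#' @param elapsed optional wall time in seconds.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(net, result, xi, tau1, seed, path,
                             elapsed = NA_real_) {
  best <- result$best
  report <- list(
    network = list(n = net$n, density = network_density(net),
                   directed = net$directed),
    config = list(xi = xi, tau1 = tau1, seed = seed,
                  restarts = length(result$r_values)),
    restart_r = result$r_values,
    attraction_rate = result$attraction_rate,
    best_r = best$best_r,
    core = if (!is.null(best$best_partition))
      net$labels[unclass(best$best_partition)] else character(0),
    elapsed_seconds = elapsed)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
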