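# File formats: square-matrix CSV/TSV, edge-list TSV, GraphML. Weights are
# written with full precision (%.17g) so write-then-read reproduces them
# bit-exactly; output ordering is deterministic (node IDs ascending, edges
# lexicographic). Node IDs are 1-based in every dialect.

.fmtW <- function(x) sprintf("%.17g", x)

.EDGE_HEADER <- c("node_i", "node_j", "weight")

.detectFormat <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "graphml") return("graphml")
  first <- readLines(path, n = 1L)
  if (identical(strsplit(first, "[\t,]")[[1]][1:3], .EDGE_HEADER))
    return("edgelist")
  "matrix"
}

#' Read a weighted network from a file
#'
#' Supported dialects:
#' \describe{
#'   \item{matrix}{square CSV (`.csv`, comma) or TSV (tab) of weights, with
#'     an optional header row of node IDs;}
#'   \item{edgelist}{TSV with header `node_i  node_j  weight`, 1-based node
#'     IDs, each symmetric edge listed once (\eqn{i < j}); absent pairs
#'     become structural zeros;}
#'   \item{graphml}{weighted undirected GraphML, weight as edge attribute
#'     `weight`.}
#' }
#' `format = "auto"` (default) uses the `.graphml` extension or the
#' edge-list header, falling back to the matrix dialect.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"matrix"`, `"edgelist"`, `"graphml"`.
#' @return A [WeightedNetwork-class]; zero off-diagonal pairs are recorded
#'   as structural disconnections.
#' @export
readNetwork <- function(path,
                        format = c("auto", "matrix", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .detectFormat(path)
  switch(format,
         matrix = .readMatrixFile(path),
         edgelist = .readEdgeList(path),
         graphml = .readGraphML(path))
}

.readMatrixFile <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  sep <- if (ext == "csv") "," else "\t"
  firstFields <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  hasHeader <- anyNA(suppressWarnings(as.numeric(firstFields)))
  m <- as.matrix(read.table(path, sep = sep, header = hasHeader,
                            row.names = NULL, check.names = FALSE))
  rownames(m) <- NULL
  if (!is.numeric(m))
    stop("matrix file ", path, " contains non-numeric entries", call. = FALSE)
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square: ", nrow(m), " rows x ",
         ncol(m), " columns", call. = FALSE)
  bad <- which(diag(m) != 0)
  if (length(bad))
    stop("nonzero diagonal entry at row ", bad[1], " of ", path,
         call. = FALSE)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative weight at row ", neg[1, 1], ", column ", neg[1, 2],
         " of ", path, call. = FALSE)
  weightedNetwork(m, symmetric = isSymmetric(unname(m)))
}

.readEdgeList <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (!identical(names(df)[1:3], .EDGE_HEADER))
    stop("edge list ", path, " must have header: ",
         paste(.EDGE_HEADER, collapse = "\t"), call. = FALSE)
  i <- df$node_i; j <- df$node_j; w <- df$weight
  if (anyNA(i) || anyNA(j) || any(i != as.integer(i)) || any(j != as.integer(j)))
    stop("edge list node IDs must be integers", call. = FALSE)
  n <- max(i, j)
  if (any(i < 1) || any(j < 1))
    stop("unknown node ID (IDs are 1-based) at line ",
         which(i < 1 | j < 1)[1] + 1L, " of ", path, call. = FALSE)
  if (any(i == j))
    stop("self-edge at line ", which(i == j)[1] + 1L, " of ", path,
         " (diagonal must be zero)", call. = FALSE)
  if (any(w < 0))
    stop("negative weight at line ", which(w < 0)[1] + 1L, " of ", path,
         call. = FALSE)
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key))
    stop("duplicate edge at line ", which(duplicated(key))[1] + 1L, " of ",
         path, " (symmetric edges are listed once)", call. = FALSE)
  A <- matrix(0, n, n)
  A[cbind(i, j)] <- w
  A[cbind(j, i)] <- w
  weightedNetwork(A)
}

.readGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::vertex_attr(g, "id")
  if (is.null(ids)) ids <- igraph::V(g)$name
  ord <- order(as.integer(ids))
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE,
                                   type = "both")
  A <- unname(as.matrix(A)[ord, ord, drop = FALSE])
  weightedNetwork(A)
}

#' Write a weighted network to a file
#'
#' See [readNetwork()] for the dialects. Output is deterministic: node IDs
#' ascending, edges in lexicographic \eqn{(i, j)} order, weights at full
#' precision, so two writes of the same network are byte-identical and
#' write-then-read reproduces the weights bit-exactly.
#'
#' @param net A [WeightedNetwork-class].
#' @param path Output path.
#' @param format One of `"auto"` (by extension), `"matrix"`, `"edgelist"`,
#'   `"graphml"`.
#' @return Invisibly, `path`.
#' @export
writeNetwork <- function(net, path,
                         format = c("auto", "matrix", "edgelist", "graphml")) {
  stopifnot(is(net, "WeightedNetwork"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, graphml = "graphml", csv = "matrix",
                     tsv = "matrix", "matrix")
  }
  switch(format,
         matrix = .writeMatrixFile(net, path),
         edgelist = .writeEdgeList(net, path),
         graphml = .writeGraphML(net, path))
  invisible(path)
}

.writeMatrixFile <- function(net, path) {
  sep <- if (tolower(sub(".*\\.", "", path)) == "csv") "," else "\t"
  A <- net@weights
  lines <- apply(A, 1L, function(row) paste(.fmtW(row), collapse = sep))
  writeLines(lines, path)
}

## connected pairs of the pattern, lexicographic; includes zero-weight
## non-structural pairs so structure round-trips exactly
.writeEdgeList <- function(net, path) {
  fp <- freeParameterization(net@pattern)
  w <- net@weights[cbind(fp$iu, fp$ju)]
  lines <- c(paste(.EDGE_HEADER, collapse = "\t"),
             sprintf("%d\t%d\t%s", fp$iu, fp$ju, .fmtW(w)))
  writeLines(lines, path)
}

.writeGraphML <- function(net, path) {
  n <- nNodes(net)
  fp <- freeParameterization(net@pattern)
  w <- net@weights[cbind(fp$iu, fp$ju)]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns"',
    '         xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
    '         xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%d"/>', seq_len(n)),
    sprintf('    <edge source="%d" target="%d"><data key="w">%s</data></edge>',
            fp$iu, fp$ju, .fmtW(w)),
    '  </graph>',
    '</graphml>')
  writeLines(lines, path)
}

#' Write the objective trajectory of a generation run as TSV
#'
#' Columns: `iteration`, `objective`, `dr`, `dv`, `ds` (per-metric
#' differences as defined by [metricDifferences()]).
#'
#' @param result A [GenerationResult-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeTrajectory <- function(result, path) {
  stopifnot(is(result, "GenerationResult"))
  write.table(result@trajectory, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a convergence map as TSV
#'
#' Columns: `v_star`, `s_star`, `converged`, `r_achieved`, `v_achieved`,
#' `s_achieved`.
#'
#' @param map A [ConvergenceMap-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeConvergenceMap <- function(map, path) {
  stopifnot(is(map, "ConvergenceMap"))
  cols <- c("v_star", "s_star", "converged", "r_achieved", "v_achieved",
            "s_achieved")
  write.table(map@grid[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
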