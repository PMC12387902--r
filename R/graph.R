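#' Turn associations into distances
#'
#' The strictly order-reversing map `d = 1 - a`, with a zero diagonal: the
#' strongest associations become the shortest distances, so a minimum
#' spanning tree over `d` keeps the most relevant connections.
#'
#' @param a an [AssociationMatrix-class].
#' @return symmetric numeric distance matrix with zero diagonal.
#' @export
associationToDistance <- function(a) {
  stopifnot(methods::is(a, "AssociationMatrix"))
  d <- 1 - a@.Data
  diag(d) <- 0
  d
}

#' Minimum spanning tree of the variable distances
#'
#' Kruskal's algorithm with fully deterministic tie-breaking: candidate
#' edges are sorted by weight, then by the lexicographic (u, v) node-name
#' pair, so the output is byte-stable across runs and platforms. Edges are
#' annotated with the association strength `1 - d`.
#'
#' @param d symmetric distance matrix with node names as dimnames, or an
#'   [AssociationMatrix-class] (converted via [associationToDistance()]).
#' @return a [VariableGraph-class] of kind `"MST"` with exactly N - 1 edges.
#' @examples
#' a <- associationMatrix(trainAutoCM(
#'   scaleCohort(appendGroupIndicators(rorschachFixture()))))
#' g <- minimumSpanningTree(a)
#' subset(graphEdges(g), u == "INPH" | v == "INPH")
#' @export
minimumSpanningTree <- function(d) {
  if (methods::is(d, "AssociationMatrix")) d <- associationToDistance(d)
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("distance matrix must be finite")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  nodes <- rownames(d)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(d)))
  n <- length(nodes)
  if (n < 2L) {
    return(methods::new("VariableGraph", nodes = nodes,
                        edges = data.frame(u = character(), v = character(),
                                           strength = numeric()),
                        kind = "MST"))
  }
  idx <- which(upper.tri(d), arr.ind = TRUE)
  eu <- nodes[idx[, 1]]; ev <- nodes[idx[, 2]]
  # canonical orientation: u < v lexicographically
  swap <- eu > ev
  tmp <- eu[swap]; eu[swap] <- ev[swap]; ev[swap] <- tmp
  wt <- d[idx]
  ord <- order(wt, eu, ev, method = "radix")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(length(ord))
  taken <- 0L
  for (k in ord) {
    ri <- find(match(eu[k], nodes))
    rj <- find(match(ev[k], nodes))
    if (ri != rj) {
      parent[ri] <- rj
      keep[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  e <- data.frame(u = eu[keep], v = ev[keep], strength = 1 - wt[keep],
                  stringsAsFactors = FALSE)
  e <- e[order(-e$strength, e$u, e$v), , drop = FALSE]
  rownames(e) <- NULL
  methods::new("VariableGraph", nodes = nodes, edges = e, kind = "MST")
}

#' Augment a spanning tree toward a maximally regular graph
#'
#' Iterates the non-tree edges in decreasing association strength (ties
#' broken lexicographically) and adds an edge whenever the supplied
#' regularity functional strictly increases, up to `budget` additions. The
#' default functional accepts nothing, so the default output is the tree
#' itself relabelled as kind `"MRG"`; a task-specific regularity measure can
#' be plugged in without touching the rest of the pipeline.
#'
#' @param tree a [VariableGraph-class] spanning tree over `a`'s nodes.
#' @param a the [AssociationMatrix-class] the tree was derived from.
#' @param regularity `NULL` (default: no augmentation) or a function taking
#'   a [VariableGraph-class] and returning a single numeric score.
#' @param budget maximum number of edges to add (>= 0).
#' @return a [VariableGraph-class] of kind `"MRG"` whose edge set contains
#'   the tree's.
#' @export
mrgAugment <- function(tree, a, regularity = NULL, budget = Inf) {
  stopifnot(methods::is(tree, "VariableGraph"),
            methods::is(a, "AssociationMatrix"))
  if (budget < 0) stop("budget must be non-negative")
  if (!setequal(tree@nodes, rownames(a@.Data)))
    stop("tree and association matrix cover different nodes")
  g <- methods::new("VariableGraph", nodes = tree@nodes, edges = tree@edges,
                    kind = "MRG")
  if (is.null(regularity) || budget == 0) return(g)
  m <- a@.Data
  idx <- which(upper.tri(m), arr.ind = TRUE)
  cand <- data.frame(u = rownames(m)[idx[, 1]], v = rownames(m)[idx[, 2]],
                     strength = m[idx], stringsAsFactors = FALSE)
  swap <- cand$u > cand$v
  tmp <- cand$u[swap]; cand$u[swap] <- cand$v[swap]; cand$v[swap] <- tmp
  inTree <- paste(cand$u, cand$v) %in% paste(g@edges$u, g@edges$v)
  cand <- cand[!inTree, , drop = FALSE]
  cand <- cand[order(-cand$strength, cand$u, cand$v), , drop = FALSE]
  score <- regularity(g)
  added <- 0L
  for (k in seq_len(nrow(cand))) {
    if (added >= budget) break
    trial <- g
    trial@edges <- rbind(g@edges, cand[k, ])
    s2 <- regularity(trial)
    if (s2 > score) {
      g <- trial
      score <- s2
      added <- added + 1L
    }
  }
  rownames(g@edges) <- NULL
  g
}

#' @rdname accessors
#' @export
setMethod("graphNodes", "VariableGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "VariableGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("graphKind", "VariableGraph", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("nodeDegrees", "VariableGraph", function(x) {
  deg <- stats::setNames(integer(length(x@nodes)), x@nodes)
  tab <- table(c(x@edges$u, x@edges$v))
  deg[names(tab)] <- as.integer(tab)
  deg
})

setMethod("show", "VariableGraph", function(object) {
  cat(sprintf("VariableGraph (%s): %d nodes, %d edges\n", object@kind,
              length(object@nodes), nrow(object@edges)))
})

#' Convert a VariableGraph to an igraph object
#'
#' Nodes carry a `category` attribute (`"indicator"` for the INPH/DEMENZA
#' pathology nodes, `"coding"` otherwise); edges carry the full-precision
#' `strength` and a 2-decimal `label`.
#'
#' @param g a [VariableGraph-class].
#' @return an [igraph::igraph] object.
#' @export
asIgraph <- function(g) {
  stopifnot(methods::is(g, "VariableGraph"))
  vdf <- data.frame(
    name = g@nodes,
    category = ifelse(g@nodes %in% c("INPH", "DEMENZA"),
                      "indicator", "coding"),
    stringsAsFactors = FALSE)
  e <- g@edges
  e$label <- sprintf("%.2f", e$strength)
  ig <- igraph::graph_from_data_frame(e, directed = FALSE, vertices = vdf)
  ig <- igraph::set_graph_attr(ig, "kind", g@kind)
  ig
}

#' Export a variable graph to GraphML, DOT or edge-list CSV
#'
#' GraphML keeps full-precision strengths plus the 2-decimal label and
#' round-trips losslessly through [importGraph()]; DOT is write-only (for
#' graphviz rendering); CSV is a plain `u, v, strength` edge list.
#'
#' @param g a [VariableGraph-class].
#' @param path output file.
#' @param format `"graphml"`, `"dot"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
exportGraph <- function(g, path, format = c("graphml", "dot", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    e <- g@edges
    write.csv(cbind(e, kind = g@kind), path, row.names = FALSE, quote = TRUE)
  } else {
    igraph::write_graph(asIgraph(g), path, format = format)
  }
  invisible(path)
}

#' Re-import a graph written by [exportGraph()]
#'
#' @param path file written by [exportGraph()].
#' @param format `"graphml"` or `"csv"` (DOT is write-only).
#' @return a [VariableGraph-class].
#' @export
importGraph <- function(path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    kind <- if (nrow(df)) df$kind[1] else "MST"
    nodes <- sort(unique(c(df$u, df$v)))
    return(methods::new("VariableGraph", nodes = nodes,
                        edges = df[, c("u", "v", "strength")], kind = kind))
  }
  ig <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_data_frame(ig, what = "edges")
  edges <- data.frame(u = e$from, v = e$to,
                      strength = as.numeric(e$strength),
                      stringsAsFactors = FALSE)
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  kind <- igraph::graph_attr(ig, "kind")
  if (is.null(kind)) kind <- "MST"
  methods::new("VariableGraph",
               nodes = igraph::vertex_attr(ig, "name"),
               edges = edges, kind = kind)
}
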