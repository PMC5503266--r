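#' Undirected graph for the Moran process
#'
#' Lightweight container for a simple undirected graph on vertices
#' `0..n_vertices-1`: an edge matrix, the vertex degrees, and nothing else.
#' The constructor validates the structure (no self-loops, no duplicate
#' edges, no isolated vertices — every vertex needs at least one neighbor for
#' the replacement kernel to be defined).  Connectivity is *not* required at
#' construction; the fixation solvers check it themselves, because absorption
#' at fixation is only guaranteed from every state on a connected graph.
#'
#' @param edges two-column matrix (or data.frame) of 0-based vertex ids, one
#'   edge per row.
#' @param n_vertices number of vertices; defaults to `max(edges) + 1`.
#' @return an object of class `moran_graph` with fields `n_vertices`,
#'   `edges` (sorted, each row `i < j`), `degree`.
#' @seealso [make_complete()], [make_star()], [make_complete_bipartite()],
#'   [make_ell_graph()], [make_unbalanced_ell()], [read_edgelist()]
#' @export
moran_graph <- function(edges, n_vertices = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) stop("graph must have at least one edge")
  if (ncol(edges) != 2) stop("'edges' must have two columns")
  storage.mode(edges) <- "integer"
  if (anyNA(edges) || any(edges < 0)) stop("vertex ids must be nonnegative integers")
  if (is.null(n_vertices)) n_vertices <- max(edges) + 1L
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 2) stop("invalid order: need at least 2 vertices")
  # canonical row order: i < j, rows sorted
  edges <- t(apply(edges, 1, sort))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  if (max(edges) >= n_vertices) stop("edge endpoint exceeds n_vertices - 1")
  degree <- tabulate(edges + 1L, nbins = n_vertices)
  if (any(degree == 0)) {
    stop("isolated vertex (degree 0): ", paste(which(degree == 0) - 1L, collapse = ", "))
  }
  structure(list(n_vertices = n_vertices, edges = edges, degree = degree),
            class = "moran_graph")
}

#' @export
print.moran_graph <- function(x, ...) {
  cat(sprintf("moran_graph: %d vertices (0..%d), %d edges\n",
              x$n_vertices, x$n_vertices - 1L, nrow(x$edges)))
  cat("degree sequence:", paste(sort(x$degree, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

stopifnot_graph <- function(g) {
  if (!inherits(g, "moran_graph")) stop("expected a 'moran_graph' object")
  g
}

#' Is the graph connected?
#' @param g a [moran_graph()].
#' @return logical.
#' @export
is_connected <- function(g) {
  stopifnot_graph(g)
  cpp_connected(g$edges, g$n_vertices)
}

connected_or_stop <- function(g) {
  if (!is_connected(g)) {
    comp <- igraph::components(as_igraph(g))
    groups <- split(0:(g$n_vertices - 1L), comp$membership)
    stop("graph is not connected; components: ",
         paste(vapply(groups, function(v) paste0("{", paste(v, collapse = ","), "}"), ""),
               collapse = " "))
  }
  invisible(g)
}

#' Convert to an igraph object
#'
#' Vertex `i` of the `moran_graph` (0-based) becomes igraph vertex `i + 1`
#' with a `name` attribute equal to the 0-based label.
#' @param g a [moran_graph()].
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(g) {
  stopifnot_graph(g)
  ig <- igraph::graph_from_edgelist(g$edges + 1L, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$n_vertices - igraph::vcount(ig)))
  igraph::set_vertex_attr(ig, "name", value = as.character(0:(g$n_vertices - 1L)))
}

# ---------------------------------------------------------------------------
# Generators
# ---------------------------------------------------------------------------

#' Complete graph K_N
#'
#' Every pair of distinct vertices is adjacent.  Complete graphs are
#' isothermal, so by the Circulation Theorem their fixation probability is
#' the well-mixed baseline [phi0()]; they serve as the reference structure.
#'
#' @param n_vertices number of vertices, at least 2.
#' @return a [moran_graph()].
#' @export
make_complete <- function(n_vertices) {
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 2) stop("invalid order: need n_vertices >= 2")
  moran_graph(t(combn(0:(n_vertices - 1L), 2)), n_vertices)
}

#' Star graph K_{1,m}
#'
#' A center (vertex `m`, degree `m`) connected to `m` peripheral leaves
#' (vertices `0..m-1`, degree 1).  The classic amplifier of selection.
#'
#' @param m number of leaves, at least 1.
#' @return a [moran_graph()].
#' @export
make_star <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1) stop("invalid order: need m >= 1")
  moran_graph(cbind(0:(m - 1L), m), m + 1L)
}

#' Complete bipartite graph K_{a,b}
#'
#' Vertices `0..a-1` form the first part (degree `b`), `a..a+b-1` the second
#' (degree `a`); edges run exactly between parts.  `K_{1,m}` is the star.
#'
#' @param a,b part sizes, each at least 1.
#' @return a [moran_graph()].
#' @export
make_complete_bipartite <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (is.na(a) || is.na(b) || a < 1 || b < 1) stop("invalid order: need a, b >= 1")
  moran_graph(as.matrix(expand.grid(0:(a - 1L), a + 0:(b - 1L))), a + b)
}

#' Cycle graph C_N
#'
#' Vertex-transitive, hence isothermal: a second reference family on which
#' the exact solver must reproduce the well-mixed formula.
#'
#' @param n_vertices number of vertices, at least 3.
#' @return a [moran_graph()].
#' @export
make_cycle <- function(n_vertices) {
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 3) stop("invalid order: need n_vertices >= 3")
  v <- 0:(n_vertices - 1L)
  moran_graph(cbind(v, c(v[-1], 0L)), n_vertices)
}

#' Balanced ell-graph of order 2n + 2
#'
#' Take the complete graph `K_{2n}` and split its vertices into two halves A
#' (`0..n-1`) and B (`n..2n-1`).  Add two extra vertices: `u = 2n`, adjacent
#' to all of A and to `v`; and `v = 2n + 1`, adjacent to all of B and to
#' `u`.  Clique vertices have degree `2n`, extra vertices degree `n + 1`.
#' Swapping `(A, u)` with `(B, v)` is a graph automorphism; together with
#' permutations within each half it generates the symmetry that
#' [reduced_fixation()] exploits.
#'
#' The balanced members of this family are suppressors of selection: their
#' average fixation probability lies strictly below the well-mixed baseline
#' for every fitness r > 1 (and strictly above it for r < 1).
#'
#' @param n half-size of the central clique, at least 2.
#' @return a [moran_graph()] of order `2n + 2`.
#' @export
make_ell_graph <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("invalid order: need n >= 2")
  make_unbalanced_ell(p = n, q = n)
}

#' Unbalanced ell-graph
#'
#' Variant of [make_ell_graph()] in which the central clique `K_{p+q}` is
#' split unevenly: extra vertex `u = p + q` is adjacent to the `p`-part
#' (`0..p-1`) and to `v`; extra vertex `v = p + q + 1` is adjacent to the
#' `q`-part (`p..p+q-1`) and to `u`.  `p = q = n` recovers the balanced
#' ell-graph.  Unbalancing the split can flip the family from suppressor to
#' amplifier above some fitness threshold.
#'
#' @param p,q part sizes of the central clique split, each at least 1.
#' @param total_order optional consistency check; must equal `p + q + 2`.
#' @return a [moran_graph()] of order `p + q + 2`.
#' @export
make_unbalanced_ell <- function(p, q, total_order = NULL) {
  p <- as.integer(p); q <- as.integer(q)
  if (is.na(p) || is.na(q) || p < 1 || q < 1) stop("invalid order: need p, q >= 1")
  if (!is.null(total_order) && p + q + 2L != as.integer(total_order)) {
    stop(sprintf("inconsistent spec: p + q + 2 = %d but total_order = %d",
                 p + q + 2L, as.integer(total_order)))
  }
  nc <- p + q
  clique <- t(combn(0:(nc - 1L), 2))
  u <- nc; v <- nc + 1L
  spokes <- rbind(
    if (p > 0) cbind(0:(p - 1L), u),
    if (q > 0) cbind(p + 0:(q - 1L), v),
    c(u, v))
  moran_graph(rbind(clique, spokes), nc + 2L)
}

# ---------------------------------------------------------------------------
# Temperature / isothermality
# ---------------------------------------------------------------------------

#' Vertex temperature
#'
#' The temperature of vertex `i` is `T_i = sum over neighbors j of 1/d_j`:
#' the total rate at which `i` is replaced by offspring of its neighbors.
#' Computed exactly.
#'
#' @param g a [moran_graph()].
#' @param v 0-based vertex id, or `NULL` for all vertices.
#' @return canonical rational string(s).
#' @examples
#' vertex_temperature(make_star(3), 3)   # center: "3"
#' @export
vertex_temperature <- function(g, v = NULL) {
  stopifnot_graph(g)
  temps <- cpp_vertex_temperatures(g$edges, g$n_vertices)
  if (is.null(v)) return(temps)
  v <- as.integer(v)
  if (anyNA(v) || any(v < 0) || any(v >= g$n_vertices)) stop("invalid vertex id")
  temps[v + 1L]
}

#' Is the graph isothermal?
#'
#' A graph is isothermal when every vertex has the same temperature; by the
#' Circulation Theorem its fixation probability then equals the well-mixed
#' baseline [phi0()] exactly.  The comparison is exact rational equality.
#'
#' @param g a connected [moran_graph()].
#' @return logical.
#' @export
is_isothermal <- function(g) {
  stopifnot_graph(g)
  length(unique(cpp_vertex_temperatures(g$edges, g$n_vertices))) == 1L
}

# ---------------------------------------------------------------------------
# Enumeration / canonical form
# ---------------------------------------------------------------------------

#' Canonical form of a small graph
#'
#' Key string identifying the isomorphism class: the lexicographically
#' minimal upper-triangle adjacency bit-string over vertex orderings.  With
#' `full = TRUE` all `N!` orderings are tried (the defining brute force,
#' feasible for `N <= 8`); the default restricts to orderings compatible
#' with iterated-degree invariant classes, which yields the same equivalence
#' relation at a fraction of the cost.
#'
#' @param g a [moran_graph()] with at most 8 vertices.
#' @param full use the brute-force key (same classes, slower).
#' @return character key; two graphs get equal keys iff isomorphic (keys of
#'   the two modes differ from each other; compare like with like).
#' @export
canonical_form <- function(g, full = FALSE) {
  stopifnot_graph(g)
  cpp_canonical_key(g$edges, g$n_vertices, full)
}

#' Enumerate connected graphs up to isomorphism
#'
#' One representative per isomorphism class of connected simple graphs on
#' `n_vertices` vertices, generated by exhaustive scan over all labeled
#' graphs with canonical-form deduplication.  Refused above 7 vertices
#' (combinatorial blow-up: 11117 classes at 8, and the labeled scan grows as
#' `2^(N(N-1)/2)`).
#'
#' @param n_vertices between 2 and 7.
#' @return list of [moran_graph()] objects in deterministic (canonical key)
#'   order; lengths for N = 2..7 are 1, 2, 6, 21, 112, 853.
#' @export
enumerate_connected_graphs <- function(n_vertices) {
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 2) stop("invalid order: need n_vertices >= 2")
  if (n_vertices > 7) stop("enumeration refused for n_vertices > 7 (combinatorial blow-up)")
  lapply(cpp_enumerate_connected(n_vertices), moran_graph, n_vertices = n_vertices)
}

# ---------------------------------------------------------------------------
# Edge-list text format
# ---------------------------------------------------------------------------

#' Read / write the edge-list text format
#'
#' One edge per line: two whitespace-separated 0-based integer vertex ids.
#' Lines starting with `#` are comments.  The reader validates the structure
#' through the [moran_graph()] constructor; the writer emits edges sorted
#' with `i < j`.
#'
#' @param path file path.
#' @param n_vertices optional vertex count (otherwise `max id + 1`).
#' @return `read_edgelist()`: a [moran_graph()]; `write_edgelist()`: `path`,
#'   invisibly.
#' @export
read_edgelist <- function(path, n_vertices = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no edges in ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop("malformed edge line(s): ", paste(lines[bad], collapse = "; "))
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("non-integer vertex id in ", path)
  moran_graph(m, n_vertices)
}

#' @rdname read_edgelist
#' @param g a [moran_graph()].
#' @export
write_edgelist <- function(g, path) {
  stopifnot_graph(g)
  writeLines(paste(g$edges[, 1], g$edges[, 2]), path)
  invisible(path)
}
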