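#' Edge clustering coefficient
#'
#' For an interaction between proteins i and j,
#' \deqn{ECC_{ij} = \frac{Z_{ij} + 1}{\min(d_i, d_j)}}
#' where \eqn{Z_{ij}} is the number of triangles the edge participates in
#' and \eqn{d_i, d_j} the endpoint degrees.  On a simple graph the value
#' lies in (0, 1]; it measures how embedded an interaction is in locally
#' dense neighborhood structure.
#'
#' @param net Undirected simple `igraph` network.
#' @param edges Optional two-column character matrix (or vector of length
#'   2 for a single edge) of endpoint names; default all edges of `net`,
#'   in `igraph` edge order.
#' @return Numeric vector of coefficients, one per requested edge.
#' @export
edge_clustering <- function(net, edges = NULL) {
  stopifnot(igraph::is_igraph(net))
  if (is.null(edges)) {
    ends <- igraph::as_edgelist(net, names = FALSE)
  } else {
    if (is.vector(edges)) edges <- matrix(edges, ncol = 2L)
    ends <- cbind(match(edges[, 1L], igraph::V(net)$name),
                  match(edges[, 2L], igraph::V(net)$name))
    if (anyNA(ends)) stop("edge endpoint not in network")
    eid <- igraph::get_edge_ids(net, t(ends))
    if (any(eid == 0L)) stop("requested edge not present in network")
  }
  if (nrow(ends) == 0L) return(numeric(0L))
  adj <- igraph::as_adj_list(net)
  deg <- igraph::degree(net)
  vapply(seq_len(nrow(ends)), function(k) {
    i <- ends[k, 1L]; j <- ends[k, 2L]
    z <- length(intersect(as.integer(adj[[i]]), as.integer(adj[[j]])))
    (z + 1) / min(deg[[i]], deg[[j]])
  }, numeric(1L))
}

#' Rescaled Pearson co-expression similarity
#'
#' Pearson correlation of two expression vectors, mapped from
#' \eqn{[-1, 1]} to \eqn{[0, 1]} via \eqn{(r + 1)/2}.  When either vector
#' has zero variance the correlation is undefined; the raw value is taken
#' as 0 (rescaled 0.5), i.e. no co-expression evidence either way.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return Similarity in `[0, 1]`.
#' @export
coexpression_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("expression vectors differ in length")
  if (length(x) < 2L) stop("need at least 2 time points")
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)
  (r + 1) / 2
}

#' Weight a refined network by topology and co-expression
#'
#' Assigns every interaction the weight
#' \deqn{W_{ij} = ECC_{ij} \times \frac{PCC_{ij} + 1}{2}}
#' combining local topological cohesiveness ([edge_clustering()]) with
#' co-expression strength ([coexpression_similarity()]).  Weights lie in
#' `[0, 1]`.  Endpoints without expression data get the neutral rescaled
#' correlation 0.5 (this only arises when refinement kept such edges).
#'
#' @param net Undirected simple `igraph` network (normally the refined
#'   network).
#' @param expr Numeric expression matrix, rownames = gene ids.
#' @return `net` with an edge attribute `weight`.
#' @export
weight_network <- function(net, expr) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) == 0L) {
    igraph::E(net)$weight <- numeric(0L)
    return(net)
  }
  ecc <- edge_clustering(net)
  ends <- igraph::as_edgelist(net, names = TRUE)
  ia <- match(ends[, 1L], rownames(expr))
  ib <- match(ends[, 2L], rownames(expr))
  pcc <- rep(0.5, nrow(ends))
  both <- !is.na(ia) & !is.na(ib)
  for (k in which(both)) {
    pcc[k] <- coexpression_similarity(expr[ia[k], ], expr[ib[k], ])
  }
  igraph::E(net)$weight <- ecc * pcc
  net
}

#' Weighted degree (sum of incident edge weights)
#'
#' @param net Weighted `igraph` network (see [weight_network()]).
#' @param v Optional vertex name(s); default all vertices.
#' @return Named numeric vector of weighted degrees; isolated vertices
#'   score 0.
#' @export
weighted_degree <- function(net, v = NULL) {
  stopifnot(igraph::is_igraph(net))
  if (is.null(v)) v <- igraph::V(net)
  else if (!all(v %in% igraph::V(net)$name)) stop("unknown vertex name")
  igraph::strength(net, vids = v, weights = igraph::E(net)$weight)
}

#' Participation degree in protein complexes
#'
#' Scores how strongly each protein takes part in known protein
#' complexes, on the weighted refined network.  For a protein contained
#' in complexes (direct participation), the score sums, over every
#' complex containing it, its weighted degree restricted to co-members of
#' that complex; an interaction shared with a partner present in several
#' common complexes therefore counts once per complex, so multi-complex
#' proteins score higher.  A protein outside all complexes (indirect
#' participation) scores the summed weights of its interactions with
#' complexed neighbors.  Proteins with neither score 0.  Complexes never
#' create interactions: only edges of the network contribute.
#'
#' @param net Weighted `igraph` network (see [weight_network()]).
#' @param cat A `complex_catalogue`.
#' @param v Optional vertex name(s); default all vertices.
#' @return Named numeric vector of participation scores (>= 0).
#' @export
complex_participation <- function(net, cat, v = NULL) {
  stopifnot(igraph::is_igraph(net), inherits(cat, "complex_catalogue"))
  ids <- igraph::V(net)$name
  if (is.null(v)) v <- ids
  else if (!all(v %in% ids)) stop("unknown vertex name")
  w <- igraph::E(net)$weight
  if (is.null(w)) stop("network is not weighted; run weight_network() first")
  ends <- igraph::as_edgelist(net, names = TRUE)
  # incident edge index per vertex
  inc <- igraph::incident_edges(net, igraph::V(net))
  memb <- complex_membership(cat)
  in_any <- complexed_proteins(cat)

  score_one <- function(name) {
    eids <- as.integer(inc[[match(name, ids)]])
    if (length(eids) == 0L) return(0)
    nb <- ifelse(ends[eids, 1L] == name, ends[eids, 2L], ends[eids, 1L])
    wv <- w[eids]
    own <- memb[[name]]
    if (!is.null(own)) {
      sum(vapply(own, function(cx) sum(wv[nb %in% cat[[cx]]]), numeric(1L)))
    } else {
      sum(wv[nb %in% in_any])
    }
  }
  out <- vapply(v, score_one, numeric(1L))
  names(out) <- v
  out
}
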