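#' Second-order neighborhood subgraph of a protein
#'
#' The subgraph induced on a protein together with its direct (level-1)
#' and indirect (level-2) neighbors — every vertex within graph distance
#' 2 of the center — including all network edges between those vertices.
#'
#' @param net Undirected `igraph` network with vertex names.
#' @param v Center vertex name.
#' @return A `neighborhood_subgraph`: list with `center`, `members`
#'   (character vector), `graph` (the induced `igraph` subgraph) and `Ns`
#'   (member count).
#' @export
neighborhood_subgraph <- function(net, v) {
  stopifnot(igraph::is_igraph(net))
  if (!v %in% igraph::V(net)$name) stop("unknown vertex name: ", v)
  members <- igraph::ego(net, order = 2L, nodes = v)[[1L]]
  sub <- igraph::induced_subgraph(net, members)
  structure(
    list(center = v, members = members$name, graph = sub,
         Ns = length(members)),
    class = "neighborhood_subgraph"
  )
}

#' @export
print.neighborhood_subgraph <- function(x, ...) {
  cat(sprintf("Neighborhood subgraph of %s: %d proteins, %d interactions\n",
              x$center, x$Ns, igraph::ecount(x$graph)))
  invisible(x)
}

#' Shared-annotation similarity of two proteins
#'
#' \deqn{SG_{ij} = \frac{|G_i \cap G_j|^2}{|G_i|\,|G_j|}}
#' where \eqn{G_i} is the GO term set of protein i.  Zero when either
#' protein is unannotated; 1 when the sets are identical; always in
#' `[0, 1]` (Cauchy-Schwarz).
#'
#' @param ann Named list of GO term sets (see [read_annotations()]).
#' @param i,j Protein identifiers.
#' @return Similarity in `[0, 1]`.
#' @export
go_overlap <- function(ann, i, j) {
  set_overlap(ann[[i]], ann[[j]])
}

#' Shared-complex similarity of two proteins
#'
#' \deqn{SC_{ij} = \frac{|C_i \cap C_j|^2}{|C_i|\,|C_j|}}
#' where \eqn{C_i} is the set of complexes containing protein i.  Zero
#' when either protein belongs to no complex.
#'
#' @param cat A `complex_catalogue`.
#' @param i,j Protein identifiers.
#' @return Similarity in `[0, 1]`.
#' @export
complex_overlap <- function(cat, i, j) {
  memb <- complex_membership(cat)
  set_overlap(memb[[i]], memb[[j]])
}

set_overlap <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0)
  length(intersect(a, b))^2 / (na * nb)
}

#' Subgraph density score
#'
#' For each protein, the interactions inside its second-order
#' neighborhood subgraph are weighted by shared GO annotations
#' ([go_overlap()]) plus shared complex membership ([complex_overlap()]),
#' and the density is
#' \deqn{SD(v) = \frac{2 \sum_{(i,j) \in E_s} (SG_{ij} + SC_{ij})}{N_s (N_s - 1)}}
#' where \eqn{E_s} are the subgraph's edges and \eqn{N_s} its vertex
#' count (center included).  A protein whose subgraph has at most one
#' vertex scores 0.  Values lie in `[0, 2]`, attaining 2 only on a clique
#' whose members all share identical annotations and complexes.
#'
#' @param net Undirected `igraph` network (normally the refined network).
#' @param ann Named list of GO term sets.
#' @param cat A `complex_catalogue`.
#' @param v Optional vertex name(s); default all vertices.
#' @return Named numeric vector of densities.
#' @export
subgraph_density <- function(net, ann, cat, v = NULL) {
  stopifnot(igraph::is_igraph(net), inherits(cat, "complex_catalogue"))
  ids <- igraph::V(net)$name
  if (is.null(v)) v <- ids
  else if (!all(v %in% ids)) stop("unknown vertex name")
  n <- length(ids)
  ends <- igraph::as_edgelist(net, names = FALSE)
  # per-edge SG + SC, computed once and reused across overlapping subgraphs
  memb <- complex_membership(cat)
  epair <- numeric(nrow(ends))
  if (nrow(ends) > 0L) {
    for (k in seq_len(nrow(ends))) {
      a <- ids[ends[k, 1L]]; b <- ids[ends[k, 2L]]
      epair[k] <- set_overlap(ann[[a]], ann[[b]]) +
        set_overlap(memb[[a]], memb[[b]])
    }
  }
  adj <- igraph::as_adj_list(net)
  score_one <- function(name) {
    vi <- match(name, ids)
    lvl1 <- as.integer(adj[[vi]])
    members <- unique(c(vi, lvl1,
                        unlist(lapply(adj[lvl1], as.integer), use.names = FALSE)))
    ns <- length(members)
    if (ns <= 1L) return(0)
    inside <- logical(n)
    inside[members] <- TRUE
    sel <- inside[ends[, 1L]] & inside[ends[, 2L]]
    2 * sum(epair[sel]) / (ns * (ns - 1))
  }
  out <- vapply(v, score_one, numeric(1L))
  names(out) <- v
  out
}
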