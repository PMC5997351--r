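#' Score proteins by complex participation and subgraph density
#'
#' Fits the full essentiality-scoring pipeline on a protein-protein
#' interaction network:
#'
#' 1. **Refinement** — interactions whose endpoint genes are never
#'    simultaneously active (per-gene three-sigma thresholds over the
#'    expression time course) are deleted ([refine_network()]).
#' 2. **Weighting** — each remaining interaction is weighted by the edge
#'    clustering coefficient times the rescaled Pearson co-expression of
#'    its endpoints ([weight_network()]).
#' 3. **Participation degree** (PC) — each protein's weighted engagement
#'    in known protein complexes ([complex_participation()]).
#' 4. **Subgraph density** (SD) — the density of the protein's
#'    second-order neighborhood, with interactions weighted by shared GO
#'    annotations and shared complexes ([subgraph_density()]).
#' 5. **Combination** — `alpha * PC + (1 - alpha) * SD`
#'    ([pcsd_score()]), ranked descending with a deterministic tie-break.
#'
#' Proteins isolated by refinement stay in the ranking (scoring on their
#' residual subgraph structure, typically 0), so top-percentage selection
#' covers all proteins of the input network.
#'
#' @param network Undirected simple `igraph` network with vertex names
#'   (see [read_edge_list()]).
#' @param expression Numeric expression matrix, rownames = gene ids (see
#'   [read_expression()]).
#' @param complexes A `complex_catalogue` (see [read_complexes()]).
#' @param annotations Named list of GO term sets (see
#'   [read_annotations()]).
#' @param alpha Mixing parameter in `[0, 1]`; 0.8 by default.
#' @param refine Apply the expression refinement step?  `FALSE` scores
#'   the original network (ablation).
#' @param sigma_multiplier Activity-threshold multiplier, see
#'   [activity_threshold()].
#' @param keep_missing_expression Keep interactions whose endpoints lack
#'   expression data, see [refine_network()].
#' @param sd_on Topology on which subgraph density is computed:
#'   the refined network (default) or the original one (ablation).
#' @return An object of class `pcsd`: a list with
#'   \describe{
#'     \item{scores}{data frame `id`, `pc`, `sd`, `pcsd`, `rank`, ordered
#'       best-first.}
#'     \item{alpha}{the mixing parameter used.}
#'     \item{network}{the original network.}
#'     \item{refined}{the refined, weighted network actually scored.}
#'     \item{n_deleted}{number of interactions removed by refinement.}
#'   }
#' @examples
#' fx <- simulate_ppi_data(n_proteins = 30, seed = 7)
#' fit <- pcsd(fx$network, fx$expression, fx$complexes, fx$annotations)
#' head(fit$scores)
#' predict(fit, top = 10)
#' @export
pcsd <- function(network, expression, complexes, annotations,
                 alpha = 0.8, refine = TRUE, sigma_multiplier = 3,
                 keep_missing_expression = FALSE,
                 sd_on = c("refined", "original")) {
  stopifnot(igraph::is_igraph(network), is.matrix(expression),
            inherits(complexes, "complex_catalogue"), is.list(annotations))
  if (igraph::is_directed(network)) stop("network must be undirected")
  if (is.null(igraph::V(network)$name)) stop("network vertices must be named")
  sd_on <- match.arg(sd_on)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }

  refined <- if (refine) {
    refine_network(network, expression, sigma_multiplier,
                   keep_missing_expression)
  } else {
    network
  }
  weighted <- weight_network(refined, expression)
  pc <- complex_participation(weighted, complexes)
  sd_net <- if (sd_on == "refined") refined else network
  sdv <- subgraph_density(sd_net, annotations, complexes)

  ids <- igraph::V(network)$name
  pc <- pc[ids]; sdv <- sdv[ids]
  score <- pcsd_score(pc, sdv, alpha)
  ranking <- rank_proteins(score, ids)
  ord <- match(ranking, ids)
  scores <- data.frame(
    id = ids[ord], pc = unname(pc[ord]), sd = unname(sdv[ord]),
    pcsd = unname(score[ord]), rank = seq_along(ids),
    stringsAsFactors = FALSE
  )
  structure(
    list(scores = scores, alpha = alpha, network = network,
         refined = weighted,
         n_deleted = igraph::ecount(network) - igraph::ecount(refined),
         call = match.call()),
    class = "pcsd"
  )
}

#' @export
print.pcsd <- function(x, ...) {
  cat("Essentiality scores (complex participation + subgraph density)\n")
  cat(sprintf("  proteins: %d   interactions: %d (refined: %d, %d deleted)\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              igraph::ecount(x$refined), x$n_deleted))
  cat(sprintf("  alpha = %g\n", x$alpha))
  cat("Top proteins:\n")
  print(utils::head(x$scores, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.pcsd <- function(object, ...) {
  s <- object$scores
  cat(sprintf("pcsd fit: %d proteins, alpha = %g\n", nrow(s), object$alpha))
  cat(sprintf("  refinement: %d of %d interactions deleted\n",
              object$n_deleted, igraph::ecount(object$network)))
  cat("  score components:\n")
  print(rbind(pc = summary(s$pc), sd = summary(s$sd), pcsd = summary(s$pcsd)))
  cat(sprintf("  proteins with zero combined score: %d\n", sum(s$pcsd == 0)))
  invisible(object)
}

#' Extract combined essentiality scores
#'
#' @param object A `pcsd` fit.
#' @param ... Unused.
#' @return Named numeric vector of combined scores, best first.
#' @export
coef.pcsd <- function(object, ...) {
  stats::setNames(object$scores$pcsd, object$scores$id)
}

#' Predict candidate essential proteins
#'
#' Returns the identifiers ranked in the top `top` percent (cutoff
#' `round(N * top / 100)`), optionally re-mixing the two score components
#' at a different `alpha` without refitting.
#'
#' @param object A `pcsd` fit.
#' @param top Percentage of top-ranked proteins to call essential.
#' @param alpha Optional alternative mixing parameter.
#' @param rounding Cutoff rounding convention, see
#'   [count_true_essentials()].
#' @param ... Unused.
#' @return Character vector of candidate essential protein ids.
#' @export
predict.pcsd <- function(object, top = 1, alpha = NULL,
                         rounding = c("round", "floor", "ceil"), ...) {
  stopifnot(top > 0, top <= 100)
  rounding <- match.arg(rounding)
  ranking <- if (is.null(alpha)) {
    object$scores$id
  } else {
    rank_proteins(pcsd_score(object$scores$pc, object$scores$sd, alpha),
                  object$scores$id)
  }
  n <- length(ranking)
  k <- switch(rounding,
              round = round(n * top / 100),
              floor = floor(n * top / 100),
              ceil  = ceiling(n * top / 100))
  ranking[seq_len(k)]
}

#' Plot the two score components
#'
#' Scatter of subgraph density against complex participation, one point
#' per protein; the top-ranked proteins at the fitted alpha are
#' highlighted.
#'
#' @param x A `pcsd` fit.
#' @param top Percentage of top proteins to highlight.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.pcsd <- function(x, top = 5, ...) {
  s <- x$scores
  hi <- s$rank <= round(nrow(s) * top / 100)
  graphics::plot(s$pc, s$sd, pch = ifelse(hi, 19, 1),
                 col = ifelse(hi, "firebrick", "grey40"),
                 xlab = "participation degree in complexes (PC)",
                 ylab = "subgraph density (SD)", ...)
  invisible(x)
}
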