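#' Three-sigma activity threshold for one gene
#'
#' A gene is considered active at a time point when its expression meets
#' a per-gene threshold derived from its own expression curve:
#' \deqn{thr = \mu + k\,\sigma\,(1 - F), \qquad F = \frac{1}{1+\sigma^2}}
#' with \eqn{\mu} the mean, \eqn{\sigma} the (sample) standard deviation
#' of the curve and \eqn{k} the sigma multiplier (default 3).  The factor
#' \eqn{1 - F} damps the threshold for flat, low-variance curves: a
#' constant gene (\eqn{\sigma = 0}) gets `threshold == mean` and is active
#' at every point.  Activity uses "greater than or equal to".
#'
#' @param expr Numeric vector of at least 2 finite expression values.
#' @param sigma_multiplier Multiplier \eqn{k} on the damped sigma term.
#' @return An `activity_profile`: list with `mean`, `sd`, `threshold` and
#'   logical vector `active` (one element per time point).
#' @examples
#' activity_threshold(c(1, 1.2, 5, 1.1, 4.8, 1))
#' @export
activity_threshold <- function(expr, sigma_multiplier = 3) {
  if (length(expr) < 2L || !all(is.finite(expr))) {
    stop("expression vector must hold at least 2 finite values")
  }
  mu <- mean(expr)
  s <- stats::sd(expr)
  thr <- mu + sigma_multiplier * s * (1 - 1 / (1 + s^2))
  structure(
    list(mean = mu, sd = s, threshold = thr, active = expr >= thr),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf(
    "Activity profile: mean %.4g, sd %.4g, threshold %.4g, active at %d/%d points\n",
    x$mean, x$sd, x$threshold, sum(x$active), length(x$active)))
  invisible(x)
}

#' Are two genes co-expressed?
#'
#' Two proteins count as co-expressed when both genes are active at at
#' least one common time point.
#'
#' @param p,q `activity_profile` objects of equal length (see
#'   [activity_threshold()]).
#' @return Logical scalar.
#' @export
is_coexpressed <- function(p, q) {
  stopifnot(inherits(p, "activity_profile"), inherits(q, "activity_profile"))
  if (length(p$active) != length(q$active)) {
    stop("activity profiles cover different numbers of time points")
  }
  any(p$active & q$active)
}

#' Refine a PPI network with expression activity
#'
#' Deletes interactions whose two endpoint genes are never simultaneously
#' active over the expression time course, producing the refined network
#' (RPIN).  The node set is preserved — proteins that lose all their
#' interactions remain as isolated vertices, so top-percentage selection
#' still ranges over all proteins of the original data set.
#'
#' Edges with an endpoint absent from the expression matrix are deleted
#' by default (such a pair can never be observed co-expressed); set
#' `keep_missing_expression = TRUE` to retain them for sensitivity
#' analysis.
#'
#' @param net Undirected `igraph` network with vertex names.
#' @param expr Numeric expression matrix, rownames = gene ids (see
#'   [read_expression()]).
#' @param sigma_multiplier Passed to [activity_threshold()].
#' @param keep_missing_expression Keep edges whose endpoints lack
#'   expression data?
#' @return The refined `igraph` network (same vertex set, subset of
#'   edges).  The number of deleted edges is reported via [message()].
#' @export
refine_network <- function(net, expr, sigma_multiplier = 3,
                           keep_missing_expression = FALSE) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) == 0L) return(net)
  active <- activity_matrix(expr, sigma_multiplier)
  ends <- igraph::as_edgelist(net, names = TRUE)
  ia <- match(ends[, 1L], rownames(active))
  ib <- match(ends[, 2L], rownames(active))
  keep <- logical(nrow(ends))
  both <- !is.na(ia) & !is.na(ib)
  if (any(both)) {
    keep[both] <- rowSums(active[ia[both], , drop = FALSE] &
                            active[ib[both], , drop = FALSE]) > 0L
  }
  keep[!both] <- keep_missing_expression
  refined <- igraph::delete_edges(net, which(!keep))
  message("refine_network: deleted ", sum(!keep), " of ", length(keep),
          " interaction(s)")
  refined
}

# logical genes x T matrix of activity calls
activity_matrix <- function(expr, sigma_multiplier = 3) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L)
  mu <- rowMeans(expr)
  s <- apply(expr, 1L, stats::sd)
  thr <- mu + sigma_multiplier * s * (1 - 1 / (1 + s^2))
  expr >= thr
}
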