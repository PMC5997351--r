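#' Combine participation and density into one essentiality score
#'
#' The linear combination \eqn{\alpha\,PC + (1-\alpha)\,SD}.  At
#' `alpha = 1` only complex participation counts, at `alpha = 0` only
#' subgraph density; 0.8 is the standard operating point.
#'
#' @param pc Participation-degree score(s).
#' @param sd Subgraph-density score(s).
#' @param alpha Mixing parameter in `[0, 1]`.
#' @return Numeric score(s).
#' @export
pcsd_score <- function(pc, sd, alpha = 0.8) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  alpha * pc + (1 - alpha) * sd
}

#' Rank proteins by score
#'
#' Descending by score; ties broken by ascending protein identifier in
#' byte (C-locale) order, so the ranking is deterministic and independent
#' of input order and platform locale.
#'
#' @param score Named numeric vector (names = protein ids), or
#'   unnamed with `ids` supplied.
#' @param ids Optional character vector of identifiers matching `score`.
#' @return Character vector of identifiers, best first.
#' @export
rank_proteins <- function(score, ids = names(score)) {
  if (is.null(ids) || length(ids) != length(score)) {
    stop("each score needs a protein identifier")
  }
  ids[order(-score, ids, method = "radix")]
}

#' Count true essentials among the top p percent
#'
#' Selects the top `round(N * p / 100)` proteins of a ranking as
#' candidate essentials and counts how many are in the gold standard.
#' `rounding` controls the cutoff size convention ("round" uses R's
#' round-half-to-even).
#'
#' @param ranking Character vector of ids, best first (see
#'   [rank_proteins()]).
#' @param essentials Character vector of gold-standard essential ids.
#' @param p Percentage in (0, 100].
#' @param rounding Cutoff rounding convention.
#' @return Integer count.
#' @export
count_true_essentials <- function(ranking, essentials, p,
                                  rounding = c("round", "floor", "ceil")) {
  stopifnot(p > 0, p <= 100)
  rounding <- match.arg(rounding)
  k <- switch(rounding,
              round = round(length(ranking) * p / 100),
              floor = floor(length(ranking) * p / 100),
              ceil  = ceiling(length(ranking) * p / 100))
  sum(ranking[seq_len(k)] %in% essentials)
}

#' Jackknife curve of a ranking
#'
#' Element k is the number of true essentials among the top-k proteins;
#' the curve is non-decreasing with unit steps and ends at the number of
#' gold-standard essentials present in the ranking.
#'
#' @inheritParams count_true_essentials
#' @return Integer vector of length `length(ranking)`.
#' @export
jackknife_curve <- function(ranking, essentials) {
  cumsum(ranking %in% essentials)
}

#' Precision-recall curve of a ranking
#'
#' At each cutoff k, precision = TP/k and recall = TP/(number of
#' essentials present in the ranking).
#'
#' @inheritParams count_true_essentials
#' @return Data frame with columns `k`, `recall`, `precision`.
#' @export
pr_curve <- function(ranking, essentials) {
  total <- sum(ranking %in% essentials)
  if (total == 0L) {
    stop("no gold-standard essential protein present in the ranking; ",
         "recall is undefined")
  }
  tp <- cumsum(ranking %in% essentials)
  k <- seq_along(ranking)
  data.frame(k = k, recall = tp / total, precision = tp / k)
}

#' ROC curve and AUC of essentiality scores
#'
#' Sweeps the score threshold over all distinct values, computing the
#' true- and false-positive rates at each, and integrates the curve by
#' the trapezoidal rule.  Tied scores enter as a single threshold, so a
#' tied essential/non-essential block contributes 1/2 — the AUC equals
#' the Mann-Whitney probability that a random essential protein outscores
#' a random non-essential one (ties counting half).
#'
#' @param score Named numeric vector of scores (names = protein ids).
#' @param essentials Character vector of gold-standard essential ids;
#'   proteins absent from `score` are ignored.
#' @return List with `curve` (data frame `fpr`, `tpr`, anchored at
#'   (0,0) and (1,1)) and `auc`.
#' @export
roc_auc <- function(score, essentials) {
  if (is.null(names(score))) stop("scores must be named by protein id")
  lab <- names(score) %in% essentials
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one essential and one non-essential protein")
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; l <- lab[ord]
  # collapse tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a fitted ranking against a gold standard
#'
#' Runs the full evaluation protocol on a [pcsd()] fit (or any named
#' score vector): true-essential counts at the usual top percentages,
#' the jackknife curve, the precision-recall curve and the ROC/AUC.
#' The evaluation universe is the proteins of the fit; gold-standard ids
#' absent from the network are excluded from the positive class.
#'
#' @param fit A `pcsd` object, or a named numeric score vector.
#' @param essentials Character vector of gold-standard essential ids.
#' @param percents Top percentages at which to count true essentials.
#' @param rounding Cutoff rounding convention, see
#'   [count_true_essentials()].
#' @return A `pcsd_eval` object: list with `topk` (named integer vector),
#'   `jackknife`, `pr`, `roc`, `auc`, `n` (ranking size) and
#'   `n_essential` (gold-standard positives in the universe).
#' @export
evaluate_essentials <- function(fit, essentials,
                                percents = c(1, 5, 10, 15, 20, 25),
                                rounding = "round") {
  score <- if (inherits(fit, "pcsd")) stats::coef(fit) else fit
  if (is.null(names(score))) stop("scores must be named by protein id")
  ranking <- rank_proteins(score)
  ess_in <- intersect(essentials, names(score))
  if (length(ess_in) == 0L) {
    stop("no gold-standard essential protein present in the network")
  }
  topk <- vapply(percents, function(p) {
    count_true_essentials(ranking, ess_in, p, rounding)
  }, numeric(1L))
  names(topk) <- paste0("top", percents, "%")
  roc <- roc_auc(score, ess_in)
  structure(
    list(topk = topk, jackknife = jackknife_curve(ranking, ess_in),
         pr = pr_curve(ranking, ess_in), roc = roc$curve, auc = roc$auc,
         n = length(ranking), n_essential = length(ess_in),
         percents = percents),
    class = "pcsd_eval"
  )
}

#' @export
print.pcsd_eval <- function(x, ...) {
  cat("Essentiality evaluation over", x$n, "proteins (",
      x$n_essential, "gold-standard essentials )\n")
  cat("True essentials in top ranked proteins:\n")
  print(x$topk)
  cat(sprintf("ROC AUC: %.5f\n", x$auc))
  invisible(x)
}

#' Plot evaluation curves
#'
#' @param x A `pcsd_eval` object.
#' @param type Which curve to draw.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.pcsd_eval <- function(x, type = c("jackknife", "pr", "roc"), ...) {
  type <- match.arg(type)
  switch(type,
    jackknife = graphics::plot(
      seq_along(x$jackknife), x$jackknife, type = "l",
      xlab = "rank cutoff", ylab = "true essential proteins", ...),
    pr = graphics::plot(
      x$pr$recall, x$pr$precision, type = "l",
      xlab = "recall", ylab = "precision", ylim = c(0, 1), ...),
    roc = {
      graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                     xlab = "false positive rate",
                     ylab = "true positive rate", ...)
      graphics::abline(0, 1, lty = 3)
    })
  invisible(x)
}

#' Sweep the mixing parameter alpha
#'
#' Re-ranks a fit at each alpha (the participation and density components
#' are fixed, so no refitting is needed) and counts true essentials at
#' each top percentage, producing the standard alpha-sensitivity table.
#'
#' @param fit A `pcsd` object.
#' @param essentials Character vector of gold-standard essential ids.
#' @param alphas Mixing values to evaluate.
#' @param percents Top percentages.
#' @param rounding Cutoff rounding convention.
#' @return Data frame: one row per alpha, one column per percentage.
#' @export
alpha_sweep <- function(fit, essentials, alphas = seq(0, 1, by = 0.1),
                        percents = c(1, 5, 10, 15, 20, 25),
                        rounding = "round") {
  stopifnot(inherits(fit, "pcsd"))
  ess_in <- intersect(essentials, fit$scores$id)
  rows <- lapply(alphas, function(a) {
    sc <- pcsd_score(fit$scores$pc, fit$scores$sd, a)
    ranking <- rank_proteins(sc, fit$scores$id)
    vapply(percents, function(p) {
      count_true_essentials(ranking, ess_in, p, rounding)
    }, numeric(1L))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("top", percents, "%")
  cbind(alpha = alphas, out)
}
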