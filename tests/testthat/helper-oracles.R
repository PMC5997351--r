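# Independent brute-force oracles used to cross-check every pipeline
# stage.  These work directly on a plain two-column edge-list matrix and
# base-R set/sum arithmetic; they share no code with the implementation.

oracle_edges <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  matrix(as.character(el), ncol = 2L)
}

oracle_neighbors <- function(el, v) {
  unique(c(el[el[, 1L] == v, 2L], el[el[, 2L] == v, 1L]))
}

oracle_ecc <- function(el, a, b) {
  na <- oracle_neighbors(el, a)
  nb <- oracle_neighbors(el, b)
  z <- length(intersect(na, nb))
  (z + 1) / min(length(na), length(nb))
}

# Pearson correlation from raw sums, rescaled to [0, 1]
oracle_pcc_rescaled <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  r <- if (den == 0) 0 else num / den
  (r + 1) / 2
}

oracle_weight <- function(el, expr, a, b) {
  oracle_ecc(el, a, b) * oracle_pcc_rescaled(expr[a, ], expr[b, ])
}

# participation degree by literal nested enumeration over complexes
oracle_pc <- function(el, expr, complexes, v) {
  in_any <- unique(unlist(complexes, use.names = FALSE))
  nb <- oracle_neighbors(el, v)
  if (v %in% in_any) {
    s <- 0
    for (cx in complexes) {
      if (v %in% cx) {
        for (u in nb) if (u %in% cx) s <- s + oracle_weight(el, expr, v, u)
      }
    }
    s
  } else {
    s <- 0
    for (u in nb) if (u %in% in_any) s <- s + oracle_weight(el, expr, v, u)
    s
  }
}

oracle_set_overlap <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  length(intersect(a, b))^2 / (length(a) * length(b))
}

# subgraph density by explicit two-step neighborhood + pairwise sets
oracle_sd <- function(el, ann, complexes, v) {
  nb1 <- oracle_neighbors(el, v)
  nb2 <- unique(unlist(lapply(nb1, function(u) oracle_neighbors(el, u))))
  members <- unique(c(v, nb1, nb2))
  ns <- length(members)
  if (ns <= 1L) return(0)
  memb_of <- function(p) {
    names(complexes)[vapply(complexes, function(cx) p %in% cx, logical(1L))]
  }
  s <- 0
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1L]; b <- el[k, 2L]
    if (a %in% members && b %in% members) {
      s <- s + oracle_set_overlap(ann[[a]], ann[[b]]) +
        oracle_set_overlap(memb_of(a), memb_of(b))
    }
  }
  2 * s / (ns * (ns - 1))
}

# AUC as the Mann-Whitney pairwise probability, ties counting 1/2
oracle_auc <- function(score, essential_ids) {
  lab <- names(score) %in% essential_ids
  pos <- score[lab]
  neg <- score[!lab]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# tiny literal graph builder for hand examples
graph_from_pairs <- function(...) {
  pairs <- list(...)
  df <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(from = p[[1L]], to = p[[2L]], stringsAsFactors = FALSE)
  }))
  igraph::graph_from_data_frame(df, directed = FALSE)
}

# constant expression matrix: every gene active everywhere after
# thresholding, so refinement keeps all edges
constant_expression <- function(ids, t = 4L) {
  m <- matrix(rep(seq_along(ids), each = t), nrow = length(ids),
              byrow = TRUE)
  rownames(m) <- ids
  m
}
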