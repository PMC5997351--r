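#' Simulate a complete synthetic PPI study
#'
#' Generates the five inputs the scoring pipeline consumes — a PPI
#' network, a gene-expression time course, a protein-complex catalogue,
#' GO annotations and a gold-standard essential list — at toy scale with
#' known planted structure, so every pipeline stage can be checked
#' against ground truth without external data.
#'
#' The network is an Erdos-Renyi background with `n_cliques` planted
#' cliques (fully connected groups).  Expression emulates a periodic
#' metabolic-cycle compendium: 3 cycles over `n_timepoints` points, with
#' clique members sharing one block signal (common phase) plus i.i.d.
#' Gaussian noise, and background proteins carrying independent phases —
#' so within-clique co-expression is high and planted edges survive
#' refinement.  When `align_complexes` is `TRUE` the first complexes are
#' exactly the cliques, making the participation ground truth computable
#' by hand; further complexes are random, with a fraction
#' `complex_overlap` of their members drawn from already-complexed
#' proteins.  GO terms come from a shared vocabulary with clique-biased
#' sampling so shared-annotation similarity has signal.  All clique
#' members are labelled essential, topped up with random proteins to
#' `essential_fraction`.
#'
#' Identical seeds produce byte-identical fixtures.
#'
#' @param n_proteins Number of proteins.
#' @param edge_prob Background edge probability (default gives mean
#'   degree about 3 at 50 proteins, sparse like real interactomes).
#' @param n_cliques,clique_size Planted cliques (disjoint).
#' @param n_timepoints Time points in the expression course (36 emulates
#'   a 3-cycle yeast metabolic compendium).
#' @param noise_sd Gaussian noise s.d. around each expression signal.
#' @param n_complexes Total complexes (the first
#'   `min(n_cliques, n_complexes)` align with cliques when
#'   `align_complexes`).
#' @param complex_size Integer range of random-complex sizes.
#' @param complex_overlap Fraction of random-complex members drawn from
#'   already-complexed proteins.
#' @param align_complexes Align the first complexes with the planted
#'   cliques?
#' @param n_go_terms Size of the GO vocabulary.
#' @param go_per_protein Integer range of annotations per protein.
#' @param essential_fraction Fraction of proteins labelled essential.
#' @param n_missing_expression Number of background proteins left out of
#'   the expression matrix (exercises the missing-expression path).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return A `ppi_fixture`: list with `network` (igraph), `expression`
#'   (matrix), `complexes` (`complex_catalogue`), `annotations` (named
#'   list), `essentials` (character), `clique_members` (list of planted
#'   clique member ids) and `params`.
#' @examples
#' fx <- simulate_ppi_data(n_proteins = 25, seed = 1)
#' fx$network
#' @export
simulate_ppi_data <- function(n_proteins = 50,
                              edge_prob = 0.06,
                              n_cliques = 1, clique_size = 4,
                              n_timepoints = 36,
                              noise_sd = 0.25,
                              n_complexes = 4,
                              complex_size = c(3L, 6L),
                              complex_overlap = 0.2,
                              align_complexes = TRUE,
                              n_go_terms = 25,
                              go_per_protein = c(2L, 6L),
                              essential_fraction = 0.2,
                              n_missing_expression = 0,
                              seed = NULL) {
  stopifnot(n_proteins >= 1, edge_prob >= 0, edge_prob <= 1,
            n_timepoints >= 2, essential_fraction >= 0,
            essential_fraction <= 1, complex_overlap >= 0,
            complex_overlap <= 1)
  if (n_cliques * clique_size > n_proteins) {
    stop("planted cliques need ", n_cliques * clique_size,
         " proteins but only ", n_proteins, " are available")
  }
  if (!is.null(seed)) set.seed(seed)

  ids <- sprintf("P%04d", seq_len(n_proteins))
  cliques <- lapply(seq_len(n_cliques), function(i) {
    ids[((i - 1L) * clique_size + 1L):(i * clique_size)]
  })

  # background + planted edges
  g <- igraph::sample_gnp(n_proteins, edge_prob, directed = FALSE)
  igraph::V(g)$name <- ids
  for (cl in cliques) {
    idx <- match(cl, ids)
    pairs <- utils::combn(idx, 2L)
    g <- igraph::add_edges(g, as.vector(pairs))
  }
  g <- igraph::simplify(g)

  # expression: 3 periodic cycles; clique members share a phase
  tt <- seq_len(n_timepoints)
  phase <- stats::runif(n_proteins, 0, 2 * pi)
  for (i in seq_len(n_cliques)) {
    phase[match(cliques[[i]], ids)] <- phase[match(cliques[[i]][1L], ids)]
  }
  base <- stats::runif(n_proteins, 2, 6)
  expr <- t(vapply(seq_len(n_proteins), function(v) {
    base[v] + sin(2 * pi * 3 * tt / n_timepoints + phase[v]) +
      stats::rnorm(n_timepoints, 0, noise_sd)
  }, numeric(n_timepoints)))
  rownames(expr) <- ids
  colnames(expr) <- paste0("t", tt)
  if (n_missing_expression > 0) {
    bg <- setdiff(ids, unlist(cliques))
    drop <- sample(bg, min(n_missing_expression, length(bg)))
    expr <- expr[setdiff(ids, drop), , drop = FALSE]
  }

  # complexes: aligned cliques first, then random sets with overlap
  complexes <- list()
  if (align_complexes) {
    for (i in seq_len(min(n_cliques, n_complexes))) {
      complexes[[paste0("CPX", i)]] <- cliques[[i]]
    }
  }
  sizes <- seq(complex_size[1L], complex_size[2L])
  while (length(complexes) < n_complexes) {
    sz <- min(sizes[sample.int(length(sizes), 1L)], n_proteins)
    pool <- unique(unlist(complexes, use.names = FALSE))
    fresh <- setdiff(ids, pool)
    n_old <- min(length(pool), round(sz * complex_overlap))
    n_new <- min(length(fresh), sz - n_old)
    n_old <- min(length(pool), sz - n_new)  # top up when fresh ids run out
    members <- c(if (n_old > 0) sample(pool, n_old),
                 if (n_new > 0) sample(fresh, n_new))
    complexes[[paste0("CPX", length(complexes) + 1L)]] <- sort(members)
  }
  complexes <- as_complex_catalogue(complexes)

  # GO annotations: clique-biased vocabulary
  vocab <- sprintf("GO:%07d", seq_len(n_go_terms))
  block_terms <- lapply(seq_len(n_cliques), function(i) {
    vocab[((i - 1L) * 5L) %% n_go_terms + seq_len(min(5L, n_go_terms))]
  })
  annotations <- lapply(seq_len(n_proteins), function(v) {
    k <- sample(seq(go_per_protein[1L], go_per_protein[2L]), 1L)
    block <- which(vapply(cliques, function(cl) ids[v] %in% cl, logical(1L)))
    if (length(block) == 1L) {
      bt <- block_terms[[block]]
      n_bias <- min(length(bt), k)
      c(sample(bt, n_bias),
        if (k > n_bias) sample(setdiff(vocab, bt), k - n_bias))
    } else {
      sample(vocab, k)
    }
  })
  names(annotations) <- ids

  # essential labels: planted structure plus random fill
  n_ess <- round(n_proteins * essential_fraction)
  essentials <- unique(unlist(cliques))[seq_len(min(n_ess, n_cliques * clique_size))]
  extra <- n_ess - length(essentials)
  if (extra > 0) {
    essentials <- c(essentials, sample(setdiff(ids, essentials), extra))
  }
  essentials <- sort(essentials)

  structure(
    list(network = g, expression = expr, complexes = complexes,
         annotations = annotations, essentials = essentials,
         clique_members = cliques,
         params = list(n_proteins = n_proteins, edge_prob = edge_prob,
                       n_cliques = n_cliques, clique_size = clique_size,
                       n_timepoints = n_timepoints, noise_sd = noise_sd,
                       essential_fraction = essential_fraction,
                       seed = seed)),
    class = "ppi_fixture"
  )
}

#' @export
print.ppi_fixture <- function(x, ...) {
  cat(sprintf(
    "Synthetic PPI study: %d proteins, %d interactions, %d time points\n",
    igraph::vcount(x$network), igraph::ecount(x$network),
    ncol(x$expression)))
  cat(sprintf("  %d complexes, %d essential proteins, %d planted clique(s)\n",
              length(x$complexes), length(x$essentials),
              length(x$clique_members)))
  invisible(x)
}

#' Write a synthetic fixture to disk
#'
#' Emits the five files in exactly the formats the package readers
#' consume: `network.txt` (edge list), `expression.tsv`, `complexes.txt`,
#' `annotations.txt` and `essentials.txt`.  Reading them back round-trips
#' to equal structures.
#'
#' @param fixture A `ppi_fixture` (see [simulate_ppi_data()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the five file paths.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "ppi_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "network.txt"),
    expression = file.path(dir, "expression.tsv"),
    complexes = file.path(dir, "complexes.txt"),
    annotations = file.path(dir, "annotations.txt"),
    essentials = file.path(dir, "essentials.txt")
  )
  write_edge_list(fixture$network, paths[["network"]])
  expr <- fixture$expression
  utils::write.table(
    data.frame(id = rownames(expr), expr, check.names = FALSE),
    paths[["expression"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(
    vapply(names(fixture$complexes), function(cx) {
      paste(c(cx, fixture$complexes[[cx]]), collapse = "\t")
    }, character(1L)),
    paths[["complexes"]])
  writeLines(
    vapply(names(fixture$annotations), function(p) {
      paste(c(p, fixture$annotations[[p]]), collapse = "\t")
    }, character(1L)),
    paths[["annotations"]])
  writeLines(fixture$essentials, paths[["essentials"]])
  invisible(paths)
}
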