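#' Read a protein-protein interaction edge list
#'
#' Reads a plain-text edge list (two whitespace- or tab-separated protein
#' identifier columns per line, extra columns ignored) into an undirected
#' simple [igraph][igraph::graph] network.  Self-interactions and repeated
#' interactions are dropped, matching the standard preprocessing of the
#' yeast interactome benchmarks (DIP, Krogan, MIPS, Gavin); the number of
#' dropped records is reported via [message()].  Lines starting with `#`
#' and blank lines are ignored.  Protein identifiers are opaque strings
#' matched exactly (no case folding, no synonym mapping).
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph` graph with vertex names.
#' @seealso [write_edge_list()], [read_expression()]
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read edge list: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (!any(keep)) {
    warning("empty edge list: ", path)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  lineno <- which(keep)
  tokens <- strsplit(lines[keep], "[ \t]+")
  bad <- which(lengths(tokens) < 2L)
  if (length(bad) > 0L) {
    stop("parse error in ", path, ": line ", lineno[bad[1L]],
         " has fewer than 2 fields")
  }
  a <- vapply(tokens, `[[`, character(1L), 1L)
  b <- vapply(tokens, `[[`, character(1L), 2L)
  self <- a == b
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key) & !self
  n_dropped <- sum(self) + sum(dup)
  if (n_dropped > 0L) {
    message("read_edge_list: dropped ", sum(self), " self-interaction(s) and ",
            sum(dup), " repeated interaction(s)")
  }
  ok <- !self & !dup
  igraph::graph_from_data_frame(
    data.frame(from = a[ok], to = b[ok], stringsAsFactors = FALSE),
    directed = FALSE
  )
}

#' Write a network as a plain-text edge list
#'
#' Writes one interaction per line, two tab-separated protein identifiers.
#' Reading the result back with [read_edge_list()] round-trips the node
#' and edge sets (isolated vertices, which an edge list cannot represent,
#' are lost).
#'
#' @param net An undirected `igraph` network with vertex names.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-expression matrix
#'
#' Reads a tabular file whose first column holds gene/protein identifiers
#' and whose remaining columns hold expression values over T time points
#' (for the yeast metabolic-cycle compendium GSE3431, T = 36).  Tab,
#' comma or whitespace separation is accepted; a header row is detected
#' and skipped when its value cells are non-numeric.  Duplicated gene
#' identifiers are resolved by keeping the first occurrence (with a
#' warning).
#'
#' @param path Path to the expression table.
#' @return A numeric matrix, genes in rows (rownames = identifiers),
#'   time points in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read expression table: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty expression table: ", path)
  sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else "[ \t]+"
  tokens <- strsplit(trimws(lines), sep)
  ncols <- lengths(tokens)
  # header row: value fields non-numeric
  first_vals <- suppressWarnings(as.numeric(tokens[[1L]][-1L]))
  has_header <- length(tokens) > 1L && length(first_vals) > 0L &&
    anyNA(first_vals)
  if (has_header) {
    tokens <- tokens[-1L]
    ncols <- ncols[-1L]
    if (length(tokens) == 0L) stop("expression table has a header but no rows")
  }
  if (length(unique(ncols)) != 1L) {
    stop("parse error in ", path, ": inconsistent column count (row ",
         which(ncols != ncols[1L])[1L], ")")
  }
  if (ncols[1L] < 3L) {
    stop("expression table needs at least 2 time-point columns")
  }
  ids <- vapply(tokens, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(tokens), ncol = ncols[1L] - 1L)
  for (i in seq_along(tokens)) {
    v <- suppressWarnings(as.numeric(tokens[[i]][-1L]))
    if (anyNA(v)) {
      stop("parse error in ", path, ": non-numeric value at row ", i,
           ", column ", which(is.na(v))[1L] + 1L)
    }
    vals[i, ] <- v
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    warning("read_expression: ", sum(dup),
            " duplicated gene id(s); keeping first occurrence")
    vals <- vals[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  rownames(vals) <- ids
  colnames(vals) <- paste0("t", seq_len(ncol(vals)))
  vals
}

#' Read a protein-complex catalogue
#'
#' One complex per line: an optional complex identifier followed by the
#' member protein identifiers, whitespace- or tab-separated.  Records
#' with no members are skipped with a warning.
#'
#' @param path Path to the complex file.
#' @param has_ids Logical; does the first token of each line name the
#'   complex (default `TRUE`)?  With `FALSE` every token is a member and
#'   complexes are named `C1`, `C2`, ...
#' @return A `complex_catalogue`: a named list of character vectors of
#'   member identifiers.
#' @seealso [complex_membership()], [complexed_proteins()]
#' @export
read_complexes <- function(path, has_ids = TRUE) {
  if (!file.exists(path)) {
    stop("cannot read complex catalogue: file not found: ", path)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tokens <- strsplit(lines, "[ \t]+")
  if (has_ids) {
    ids <- vapply(tokens, `[[`, character(1L), 1L)
    members <- lapply(tokens, function(x) unique(x[-1L]))
  } else {
    ids <- paste0("C", seq_along(tokens))
    members <- lapply(tokens, unique)
  }
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("read_complexes: skipped ", sum(empty), " empty complex record(s)")
    ids <- ids[!empty]
    members <- members[!empty]
  }
  names(members) <- ids
  as_complex_catalogue(members)
}

#' Construct a complex catalogue from a named list
#'
#' @param x Named list of character vectors (complex id -> member ids).
#' @return A `complex_catalogue` object.
#' @export
as_complex_catalogue <- function(x) {
  stopifnot(is.list(x))
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("complexes must have unique names")
  }
  if (any(lengths(x) == 0L)) stop("every complex must have at least 1 member")
  x <- lapply(x, function(m) unique(as.character(m)))
  structure(x, class = "complex_catalogue")
}

#' @export
print.complex_catalogue <- function(x, ...) {
  cat("Complex catalogue:", length(x), "complexes covering",
      length(complexed_proteins(x)), "proteins\n")
  invisible(x)
}

#' Membership index of a complex catalogue
#'
#' Inverts a catalogue into a protein -> complex-name lookup.
#'
#' @param cat A `complex_catalogue`.
#' @return Named list: protein id -> character vector of complex names.
#' @export
complex_membership <- function(cat) {
  prot <- unlist(cat, use.names = FALSE)
  cplx <- rep(names(cat), lengths(cat))
  split(cplx, factor(prot, levels = unique(prot)))
}

#' Proteins contained in at least one complex
#'
#' @param cat A `complex_catalogue`.
#' @return Character vector of distinct member identifiers.
#' @export
complexed_proteins <- function(cat) {
  unique(unlist(cat, use.names = FALSE))
}

#' Read GO annotations
#'
#' Each line holds a protein identifier followed by its GO term
#' identifiers.  A protein listed on several lines gets the union of its
#' term sets.  Proteins absent from the file are treated downstream as
#' having an empty annotation set.
#'
#' @param path Path to the annotation file.
#' @return Named list: protein id -> character vector of GO term ids.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read annotations: file not found: ", path)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tokens <- strsplit(lines, "[ \t]+")
  ids <- vapply(tokens, `[[`, character(1L), 1L)
  terms <- lapply(tokens, function(x) x[-1L])
  out <- lapply(split(terms, factor(ids, levels = unique(ids))),
                function(l) unique(unlist(l, use.names = FALSE)))
  out
}

#' Read a gold-standard essential-protein list
#'
#' One identifier per line; duplicates are collapsed (set semantics).
#' Identifiers absent from any network are retained — filtering against a
#' network's node set happens at evaluation time.
#'
#' @param path Path to the list file.
#' @return Character vector of distinct identifiers.
#' @export
read_essential_list <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read essential list: file not found: ", path)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write a score table as CSV
#'
#' Columns: `id`, `pc`, `sd`, `pcsd`, `rank`, and `essential` when labels
#' are supplied.
#'
#' @param x A `pcsd` fit (see [pcsd()]) or its `scores` data frame.
#' @param path Output file path.
#' @param essentials Optional character vector of essential ids; adds a
#'   logical `essential` column.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(x, path, essentials = NULL) {
  df <- if (inherits(x, "pcsd")) x$scores else x
  if (!is.null(essentials)) df$essential <- df$id %in% essentials
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Density of a simple undirected network from its summary counts
#'
#' The identity 2E / (N (N - 1)): the fraction of possible interactions
#' that are present.  Useful for checking published interactome summary
#' tables against their own node and edge counts.
#'
#' @param n_nodes Number of proteins.
#' @param n_edges Number of interactions.
#' @return The density as a real in `[0, 1]`.
#' @export
network_density <- function(n_nodes, n_edges) {
  2 * n_edges / (n_nodes * (n_nodes - 1))
}
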