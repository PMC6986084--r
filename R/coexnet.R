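#' All-pairs Pearson correlation candidate edges
#'
#' Computes Pearson correlation between every transcript pair (rows of the
#' matrix, over samples) and emits each unordered pair meeting the cutoff
#' exactly once. Evaluation is chunked row-block by row-block; the chunked
#' result is identical to a single full-matrix evaluation. The cutoff is
#' signed (r >= r_cutoff), matching a positive-coregulation network;
#' `use_abs = TRUE` switches to |r|.
#'
#' @param x expression matrix (already low-expression filtered); at least
#'   3 samples. Constant-valued transcripts (zero variance) have undefined
#'   correlation and are dropped with a message.
#' @param r_cutoff minimum correlation for a candidate edge (default 0.8).
#' @param use_abs use the absolute correlation instead of the signed value.
#' @param chunk_size rows per block.
#' @return data.frame `a`, `b`, `r` (a earlier than b in matrix row
#'   order), with attribute `nodes` = retained transcript ids.
#' @export
pearson_all_pairs <- function(x, r_cutoff = 0.8, use_abs = FALSE,
                              chunk_size = 512L) {
  if (ncol(x) < 3) stop("need at least 3 samples for correlation")
  const <- apply(x, 1, function(v) max(v) == min(v))
  if (any(const)) {
    message(sum(const), " constant-valued transcript(s) dropped ",
            "(undefined correlation)")
    x <- x[!const, , drop = FALSE]
  }
  ids <- rownames(x)
  n <- nrow(x)
  tx <- t(x)
  out <- vector("list", ceiling(n / chunk_size))
  bi <- 0L
  for (start in seq(1L, n, by = chunk_size)) {
    end <- min(start + chunk_size - 1L, n)
    cc <- stats::cor(tx[, start:end, drop = FALSE], tx)
    rv <- if (use_abs) abs(cc) else cc
    hit <- which(rv >= r_cutoff, arr.ind = TRUE)
    gi <- start + hit[, 1L] - 1L          # global row index
    keep <- hit[, 2L] > gi                # upper triangle only
    bi <- bi + 1L
    out[[bi]] <- data.frame(a = ids[gi[keep]],
                            b = ids[hit[keep, 2L]],
                            r = cc[hit][keep],
                            stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out[seq_len(bi)])
  if (is.null(edges))
    edges <- data.frame(a = character(), b = character(), r = numeric())
  rownames(edges) <- NULL
  attr(edges, "nodes") <- ids
  edges
}

#' Highest-reciprocal-rank edge selection
#'
#' For each node, candidate partners are ranked by decreasing correlation
#' (rank 1 = strongest; ties broken by ascending partner id, which makes
#' the network invariant to input order). The HRR of a pair is the worse
#' of its two mutual ranks, HRR(i,j) = max(rank_i(j), rank_j(i)); only
#' pairs with HRR <= `hrr_limit` are kept as network edges.
#'
#' @param candidates candidate edge data.frame from [pearson_all_pairs()]
#'   (columns `a`, `b`, `r`).
#' @param hrr_limit maximum accepted HRR (default 30).
#' @param nodes node universe; defaults to the candidates' `nodes`
#'   attribute or the union of endpoint ids.
#' @return a `coexpression_graph`: list with `nodes` and `edges`
#'   (data.frame `a`, `b`, `r`, `hrr`).
#' @export
hrr_edges <- function(candidates, hrr_limit = 30L, nodes = NULL) {
  stopifnot(all(c("a", "b", "r") %in% colnames(candidates)))
  nodes <- nodes %||% attr(candidates, "nodes") %||%
    sort(unique(c(candidates$a, candidates$b)))
  if (nrow(candidates) == 0)
    return(coexpression_graph(nodes,
                              data.frame(a = character(), b = character(),
                                         r = numeric(), hrr = integer())))
  dir <- data.frame(from = c(candidates$a, candidates$b),
                    to = c(candidates$b, candidates$a),
                    r = rep(candidates$r, 2L),
                    pair = rep(seq_len(nrow(candidates)), 2L),
                    stringsAsFactors = FALSE)
  ord <- order(dir$from, -dir$r, dir$to, method = "radix")
  dir <- dir[ord, ]
  rank_in_from <- stats::ave(seq_len(nrow(dir)), dir$from, FUN = seq_along)
  hrr <- vapply(split(rank_in_from, dir$pair), max, numeric(1))
  hrr <- hrr[as.character(seq_len(nrow(candidates)))]
  keep <- hrr <= hrr_limit
  edges <- data.frame(a = candidates$a[keep], b = candidates$b[keep],
                      r = candidates$r[keep], hrr = as.integer(hrr[keep]),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  coexpression_graph(nodes, edges)
}

#' Coexpression graph container
#' @param nodes character vector of transcript ids.
#' @param edges data.frame `a`, `b`, `r`, `hrr`; no self-edges.
#' @return list of class `coexpression_graph`.
#' @export
coexpression_graph <- function(nodes, edges) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes),
            all(c("a", "b") %in% colnames(edges)))
  if (any(edges$a == edges$b)) stop("self-edges are not allowed")
  bad <- setdiff(c(edges$a, edges$b), nodes)
  if (length(bad)) stop("edge endpoints outside node set: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf("Coexpression graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# index-based adjacency list (internal)
adjacency_list <- function(graph) {
  n <- length(graph$nodes)
  ai <- match(graph$edges$a, graph$nodes)
  bi <- match(graph$edges$b, graph$nodes)
  adj <- vector("list", n)
  if (length(ai)) {
    tab <- split(c(bi, ai), c(ai, bi))
    adj[as.integer(names(tab))] <- lapply(tab, function(v) sort(unique(v)))
  }
  adj[vapply(adj, is.null, logical(1))] <- list(integer(0))
  adj
}

#' Build the coexpression network in one call
#'
#' Convenience wrapper: low-expression filter, all-pairs Pearson, HRR edge
#' selection.
#'
#' @param x expression matrix (FPKM recommended).
#' @param r_cutoff,hrr_limit,theta network thresholds (defaults 0.8, 30,
#'   0.5).
#' @param ... passed to [pearson_all_pairs()].
#' @return a `coexpression_graph`.
#' @export
build_network <- function(x, r_cutoff = 0.8, hrr_limit = 30L, theta = 0.5, ...) {
  x <- filter_low_expression(x, theta = theta)
  hrr_edges(pearson_all_pairs(x, r_cutoff = r_cutoff, ...),
            hrr_limit = hrr_limit)
}

#' Seed + first-neighbor subnetwork
#'
#' Members are the seeds plus every node sharing an edge with a seed;
#' edges are all graph edges with both ends among the members.
#'
#' @param graph a `coexpression_graph`.
#' @param seeds character vector of seed transcript ids; ids absent from
#'   the graph are reported and skipped with a warning.
#' @return list of class `subnetwork`: `seeds`, `members`, `edges`.
#' @export
extract_subnetwork <- function(graph, seeds) {
  stopifnot(inherits(graph, "coexpression_graph"))
  missing_ids <- setdiff(seeds, graph$nodes)
  if (length(missing_ids)) {
    warning(length(missing_ids), " seed id(s) absent from the graph, skipped: ",
            paste(utils::head(missing_ids, 5), collapse = ", "))
    seeds <- intersect(seeds, graph$nodes)
  }
  if (!length(seeds)) {
    warning("empty seed set; returning empty subnetwork")
    return(structure(list(seeds = character(0), members = character(0),
                          edges = graph$edges[0, ]), class = "subnetwork"))
  }
  e <- graph$edges
  touch_a <- e$a %in% seeds
  touch_b <- e$b %in% seeds
  members <- sort(unique(c(seeds, e$b[touch_a], e$a[touch_b])))
  induced <- e[e$a %in% members & e$b %in% members, , drop = FALSE]
  rownames(induced) <- NULL
  structure(list(seeds = sort(unique(seeds)), members = members,
                 edges = induced), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("Subnetwork: %d seeds, %d members, %d edges\n",
              length(x$seeds), length(x$members), nrow(x$edges)))
  invisible(x)
}

#' Convert a coexpression graph to igraph
#' @param graph a `coexpression_graph`.
#' @return an igraph object with `r` and `hrr` edge attributes.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Export a network
#'
#' `write_edge_list()` writes a TSV (node_a, node_b, r, hrr);
#' `write_graphml()` writes GraphML for visualization tools.
#'
#' @param graph a `coexpression_graph`.
#' @param path output path.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  colnames(e)[1:2] <- c("node_a", "node_b")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
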