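#' Heuristic cluster chiseling (HCCA) over node vicinity networks
#'
#' For every node the algorithm takes its node vicinity network (NVN): all
#' nodes within `nvn_steps` edges by breadth-first search. When the
#' `nvn_steps`-step vicinity already exceeds `s_max` the step depth is
#' backed off (to 2, then 1 step) so that a chiselable neighborhood
#' remains; if even the 1-step vicinity is oversized it is still chiseled
#' and discarded only if it ends outside the size bounds. Chiseling then
#' repeatedly removes, in simultaneous passes, every non-seed node with
#' strictly more edges to the outside of the current set than to the
#' inside, until a pass removes nothing; the connected component holding
#' the seed is kept. Candidates with sizes inside `[s_min, s_max]` are
#' scored by their internal-edge fraction E_in / (E_in + E_out) and
#' accepted greedily by descending score (ties: larger set, then
#' lexicographically smallest seed id), skipping candidates overlapping an
#' accepted cluster. Each remaining node joins the accepted cluster
#' containing most of its neighbors (ties: lowest cluster index); nodes
#' with no neighbor in any cluster stay unassigned.
#'
#' @param graph a `coexpression_graph`.
#' @param nvn_steps BFS depth for the vicinity (default 3).
#' @param s_min,s_max accepted cluster-core size bounds.
#' @return list of class `cluster_set`: `clusters` (list of
#'   `members`/`core`/`score`/`seed`), `membership` (named integer vector,
#'   NA = unassigned), `unassigned` (character vector).
#' @export
hcca_cluster <- function(graph, nvn_steps = 3L, s_min = 40L, s_max = 200L) {
  stopifnot(inherits(graph, "coexpression_graph"))
  if (s_min > s_max) stop("s_min must not exceed s_max")
  n <- length(graph$nodes)
  if (n == 0) stop("empty graph")
  adj <- adjacency_list(graph)
  deg <- lengths(adj)

  bfs_within <- function(seed, steps) {
    seen <- logical(n)
    seen[seed] <- TRUE
    frontier <- seed
    for (k in seq_len(steps)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!seen[nxt]]
      if (!length(nxt)) break
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    which(seen)
  }

  chisel <- function(set, seed) {
    inset <- logical(n)
    inset[set] <- TRUE
    repeat {
      cur <- which(inset)
      din <- vapply(cur, function(v) sum(inset[adj[[v]]]), numeric(1))
      dout <- deg[cur] - din
      drop <- cur[dout > din & cur != seed]
      if (!length(drop)) break
      inset[drop] <- FALSE
    }
    # keep the connected component containing the seed
    comp <- logical(n)
    comp[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[inset[nxt] & !comp[nxt]]
      comp[nxt] <- TRUE
      frontier <- nxt
    }
    which(comp)
  }

  score_of <- function(set) {
    inset <- logical(n)
    inset[set] <- TRUE
    din_tot <- sum(vapply(set, function(v) sum(inset[adj[[v]]]), numeric(1)))
    e_in <- din_tot / 2
    e_out <- sum(deg[set]) - din_tot
    if (e_in + e_out == 0) return(0)
    e_in / (e_in + e_out)
  }

  cands <- vector("list", n)
  for (seed in seq_len(n)) {
    nvn <- NULL
    for (steps in rev(seq_len(nvn_steps))) {
      nvn <- bfs_within(seed, steps)
      if (length(nvn) <= s_max || steps == 1L) break
    }
    core <- chisel(nvn, seed)
    if (length(core) < s_min || length(core) > s_max) next
    cands[[seed]] <- list(set = core, score = score_of(core), seed = seed)
  }
  cands <- cands[!vapply(cands, is.null, logical(1))]

  accepted <- list()
  if (length(cands)) {
    scores <- vapply(cands, `[[`, numeric(1), "score")
    sizes <- vapply(cands, function(c) length(c$set), numeric(1))
    seeds <- graph$nodes[vapply(cands, `[[`, numeric(1), "seed")]
    ord <- order(-scores, -sizes, seeds, method = "radix")
    taken <- logical(n)
    for (i in ord) {
      set <- cands[[i]]$set
      if (any(taken[set])) next
      taken[set] <- TRUE
      accepted[[length(accepted) + 1L]] <- cands[[i]]
    }
  }

  membership <- rep(NA_integer_, n)
  for (ci in seq_along(accepted)) membership[accepted[[ci]]$set] <- ci
  core_membership <- membership

  # attach leftovers to the accepted cluster holding most of their
  # neighbors (counted against cluster cores; ties -> lowest index)
  left <- which(is.na(membership))
  for (v in left) {
    nb <- core_membership[adj[[v]]]
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    tab <- tabulate(nb, nbins = length(accepted))
    membership[v] <- which.max(tab)
  }

  clusters <- lapply(seq_along(accepted), function(ci) {
    list(members = graph$nodes[which(membership == ci)],
         core = graph$nodes[accepted[[ci]]$set],
         score = accepted[[ci]]$score,
         seed = graph$nodes[accepted[[ci]]$seed])
  })
  structure(list(clusters = clusters,
                 membership = stats::setNames(membership, graph$nodes),
                 unassigned = graph$nodes[is.na(membership)]),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("HCCA clustering: %d clusters, %d unassigned node(s)\n",
              length(x$clusters), length(x$unassigned)))
  if (length(x$clusters)) {
    sizes <- vapply(x$clusters, function(cl) length(cl$members), numeric(1))
    cat("  sizes:", paste(utils::head(sizes, 20), collapse = ", "),
        if (length(sizes) > 20) "..." else "", "\n")
  }
  invisible(x)
}

#' Write cluster membership as TSV (transcript_id, cluster)
#' @param clusters a `cluster_set`.
#' @param path output path.
#' @export
write_cluster_membership <- function(clusters, path) {
  df <- data.frame(transcript_id = names(clusters$membership),
                   cluster = ifelse(is.na(clusters$membership), "unassigned",
                                    as.character(clusters$membership)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
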