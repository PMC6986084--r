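# Shared fixtures, generated once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# The default-design synthetic bundle (2,000 transcripts, 18 leaf samples).
fixture_bundle <- function(seed = 1L) {
  key <- paste0("bundle_", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("apomixnet_fixture_", seed))
    .fixture_cache[[key]] <- suppressMessages(make_fixtures(dir, seed = seed))
  }
  .fixture_cache[[key]]
}

# A small expression matrix with named rows/columns.
small_matrix <- function(n = 50, m = 6, seed = 42, unit = "count") {
  set.seed(seed)
  x <- matrix(rpois(n * m, lambda = 20), n, m,
              dimnames = list(sprintf("t%03d", seq_len(n)),
                              sprintf("s%02d", seq_len(m))))
  expression_matrix(x, unit = unit)
}

# Metadata for a toy 2-class design: class X with genotypes g1, g2 and
# class Y with genotype g3, `clones` clones each, leaf tissue.
toy_metadata <- function(clones = 2) {
  geno <- c(rep(c("g1", "g2"), each = clones), rep("g3", clones))
  data.frame(
    sample_id = paste0(geno, "_c", rep(seq_len(clones), 3)),
    genotype = geno,
    clone = paste0("c", rep(seq_len(clones), 3)),
    tissue = "leaf",
    phenotypic_class = c(rep("X", 2 * clones), rep("Y", clones)),
    stringsAsFactors = FALSE)
}

# Edge list for a k-clique on the given node ids.
clique_edges <- function(ids, r = 0.9) {
  cb <- t(combn(ids, 2))
  data.frame(a = cb[, 1], b = cb[, 2], r = r, stringsAsFactors = FALSE)
}

graph_from_edges <- function(edges, nodes = NULL) {
  edges$hrr <- edges$hrr %||% 1L
  coexpression_graph(nodes %||% sort(unique(c(edges$a, edges$b))), edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive enumeration of hypergeometric upper tails for all backgrounds
# up to N_max: independent combinatorial-summation oracle, vectorized.
# Returns N, K, n, j and tail = sum_{i >= j} C(K,i) C(N-K,n-i) / C(N,n).
hyper_enumeration_grid <- function(N_max = 60) {
  grid <- do.call(rbind, lapply(seq_len(N_max), function(N)
    expand.grid(N = N, K = 0:N, n = 0:N)))
  m <- pmin(grid$K, grid$n)
  sz <- m + 1L
  idx <- rep(seq_len(nrow(grid)), sz)
  j <- unlist(lapply(m, function(mm) 0:mm))
  N <- grid$N[idx]; K <- grid$K[idx]; n <- grid$n[idx]
  term <- exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))
  # grouped reverse cumulative sum over contiguous (N, K, n) groups
  cs <- cumsum(term)
  grp_end <- cumsum(sz)
  prev_end <- c(0, cs[head(grp_end, -1)])
  total <- cs[grp_end] - prev_end
  before <- (cs - term) - rep(prev_end, sz)   # in-group prefix sum
  data.frame(N = N, K = K, n = n, j = j, tail = rep(total, sz) - before)
}
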