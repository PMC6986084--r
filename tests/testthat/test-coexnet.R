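test_that("pearson candidates match a brute-force double loop, chunked or not", {
  set.seed(13)
  x <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("t%03d", 1:100), paste0("s", 1:20)))
  # add a duplicated transcript and an anti-correlated one
  x["t002", ] <- x["t001", ]
  x["t003", ] <- -x["t001", ]
  xm <- expression_matrix(abs(x) + 1, "fpkm")  # keep values non-negative
  xm["t002", ] <- xm["t001", ]
  xm["t003", ] <- max(xm["t001", ]) + 1 - xm["t001", ]

  cand <- pearson_all_pairs(xm, r_cutoff = 0.3)
  key <- function(df) paste(df$a, df$b)
  expect_true("t001 t002" %in% key(cand))
  expect_equal(cand$r[key(cand) == "t001 t002"], 1.0)
  expect_false(any(grepl("^t001 t003$|^t003 t001$", key(cand))))  # signed rule

  # brute-force oracle
  oracle <- list()
  ids <- rownames(xm)
  for (i in 1:(nrow(xm) - 1)) for (j in (i + 1):nrow(xm)) {
    r <- cor(xm[i, ], xm[j, ])
    if (r >= 0.3)
      oracle[[length(oracle) + 1]] <- data.frame(a = ids[i], b = ids[j], r = r)
  }
  oracle <- do.call(rbind, oracle)
  expect_setequal(key(cand), key(oracle))
  expect_equal(cand$r[order(key(cand))], oracle$r[order(key(oracle))],
               tolerance = 1e-12)

  # chunk contract (row order may differ between chunkings; content may not)
  cand7 <- pearson_all_pairs(xm, r_cutoff = 0.3, chunk_size = 7)
  o1 <- cand[order(key(cand)), ]; o7 <- cand7[order(key(cand7)), ]
  expect_equal(o7, o1, ignore_attr = TRUE)

  expect_error(pearson_all_pairs(xm[, 1:2], 0.8), "3 samples")
  xc <- xm; xc["t010", ] <- 5
  expect_message(pearson_all_pairs(xc, 0.3), "constant")
})

test_that("HRR ranks follow the hand enumeration and the tie rule", {
  cand <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                     r = c(0.95, 0.90, 0.85))
  g <- hrr_edges(cand, hrr_limit = 30)
  e <- g$edges[order(e_key <- paste(g$edges$a, g$edges$b)), ]
  expect_equal(e$hrr, c(1L, 2L, 2L))   # AB=1, AC=2, BC=2

  # hrr_limit = 1 keeps only mutual best partners
  g1 <- hrr_edges(cand, hrr_limit = 1)
  expect_identical(paste(g1$edges$a, g1$edges$b), "A B")

  # tied correlations rank by ascending partner id; input order irrelevant
  tied <- data.frame(a = c("n1", "n1", "n1", "n2", "n2", "n3"),
                     b = c("n2", "n3", "n4", "n3", "n4", "n4"),
                     r = 0.9)
  g2 <- hrr_edges(tied, hrr_limit = 2)
  g3 <- hrr_edges(tied[sample(nrow(tied)), ], hrr_limit = 2)
  k <- function(g) sort(paste(g$edges$a, g$edges$b, g$edges$hrr))
  expect_identical(k(g2), k(g3))
  # with all r tied, node n1's partners rank n2 < n3 < n4
  e2 <- g2$edges
  expect_identical(e2$hrr[e2$a == "n1" & e2$b == "n2"], 1L)

  # symmetry: stored HRR equals the max of both directed ranks, recomputed
  b <- fixture_bundle()
  fp <- fpkm_from_counts(b$counts, b$lengths)
  sub <- filter_low_expression(fp, 0.5)[1:300, ]
  cand2 <- pearson_all_pairs(sub, r_cutoff = 0.5)
  gg <- hrr_edges(cand2, hrr_limit = 10)
  rank_of <- function(node, partner) {
    mine <- rbind(
      data.frame(p = cand2$b[cand2$a == node], r = cand2$r[cand2$a == node]),
      data.frame(p = cand2$a[cand2$b == node], r = cand2$r[cand2$b == node]))
    mine <- mine[order(-mine$r, mine$p), ]
    which(mine$p == partner)
  }
  for (i in sample(seq_len(nrow(gg$edges)), min(25, nrow(gg$edges)))) {
    expect_identical(gg$edges$hrr[i],
                     as.integer(max(rank_of(gg$edges$a[i], gg$edges$b[i]),
                                    rank_of(gg$edges$b[i], gg$edges$a[i]))))
  }
})

test_that("subnetwork extraction is exactly seeds plus first neighbors", {
  edges <- data.frame(a = c("s", "s", "s", "x"),
                      b = c("n1", "n2", "n3", "y"), r = 0.9)
  g <- graph_from_edges(edges, nodes = c("s", "n1", "n2", "n3", "x", "y", "iso"))
  sn <- extract_subnetwork(g, "s")
  expect_setequal(sn$members, c("s", "n1", "n2", "n3"))
  expect_equal(nrow(sn$edges), 3)

  sn_iso <- extract_subnetwork(g, "iso")
  expect_identical(sn_iso$members, "iso")
  expect_equal(nrow(sn_iso$edges), 0)

  # all nodes as seeds returns the whole graph
  sn_all <- extract_subnetwork(g, g$nodes)
  expect_setequal(sn_all$members, g$nodes)
  expect_equal(nrow(sn_all$edges), nrow(g$edges))

  expect_warning(extract_subnetwork(g, c("s", "ghost")), "absent")
  expect_warning(out <- extract_subnetwork(g, character(0)), "empty")
  expect_length(out$members, 0)
})

test_that("graph exports round-trip through igraph", {
  edges <- data.frame(a = c("A", "B"), b = c("B", "C"), r = c(0.9, 0.85),
                      hrr = c(1L, 2L))
  g <- coexpression_graph(c("A", "B", "C", "D"), edges)
  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), 4)
  expect_equal(igraph::ecount(ig), 2)
  p <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, p)
  back <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::ecount(back), 2)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, p2)
  el <- read.delim(p2)
  expect_identical(colnames(el), c("node_a", "node_b", "r", "hrr"))
})
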