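test_that("median-of-ratios size factors match construction and an oracle", {
  x <- expression_matrix(
    matrix(c(5, 10, 20, 5, 10, 20), 3, 2,
           dimnames = list(paste0("g", 1:3), c("s1", "s2"))), "count")
  expect_equal(unname(estimate_size_factors(x)), c(1, 1))

  y <- expression_matrix(
    matrix(c(5, 10, 20, 10, 20, 40), 3, 2,
           dimnames = dimnames(x)), "count")
  expect_equal(unname(estimate_size_factors(y)), c(1 / sqrt(2), sqrt(2)))

  # straightforward re-implementation oracle on a random matrix
  z <- small_matrix(80, 5, seed = 9)
  s <- estimate_size_factors(z)
  ok <- apply(z, 1, function(v) all(v > 0))
  ref <- sapply(seq_len(ncol(z)), function(i) {
    median(sapply(which(ok), function(g)
      z[g, i] / exp(mean(log(z[g, ])))))
  })
  expect_equal(unname(s), ref, tolerance = 1e-12)

  z0 <- z; z0[cbind(seq_len(nrow(z0)), (seq_len(nrow(z0)) %% 5) + 1)] <- 0
  expect_error(estimate_size_factors(expression_matrix(z0, "count")),
               "pseudo-counts")
})

test_that("beta-NB marginal matches closed forms and normalizes", {
  # single sample, x = 0: f = B(alpha + r, beta) / B(alpha, beta)
  for (pars in list(c(r = 3, a = 2, b = 4), c(r = 0.5, a = 1.5, b = 2.5))) {
    expect_equal(beta_nb_logmarginal(0, pars["r"], pars["a"], pars["b"]),
                 lbeta(pars["a"] + pars["r"], pars["b"]) -
                   lbeta(pars["a"], pars["b"]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # hand value: r = 1, alpha = beta = 1, x = 0 -> 1/2
  expect_equal(exp(beta_nb_logmarginal(0, 1, 1, 1)), 0.5, tolerance = 1e-12)

  # numeric normalization over the count support
  total <- sum(vapply(0:5000, function(k)
    exp(beta_nb_logmarginal(k, r = 5, alpha = 3, beta = 2)), numeric(1)))
  expect_gte(total, 0.999)

  expect_error(beta_nb_logmarginal(0, -1, 1, 1))
})

test_that("posteriors are proper, order-invariant and monotone in separation", {
  b <- fixture_bundle()
  meta <- b$meta
  apo <- meta$sample_id[meta$phenotypic_class == "4X_apo"]
  sex <- meta$sample_id[meta$phenotypic_class == "2X_sex"]
  x <- b$counts[1:400, c(apo, sex)]
  fit <- suppressMessages(
    fit_two_group(expression_matrix(x, "count"), apo, sex))
  tab <- fit$table
  ok <- !is.na(tab$PPDE)
  expect_equal(tab$PPEE[ok] + tab$PPDE[ok], rep(1, sum(ok)))  # exact
  expect_true(all(tab$call[tab$PPDE < 0.95 | is.na(tab$PPDE)] == "not_DE"))
  expect_false(is.unsorted(fit$loglik))  # EM never decreases the loglik

  # permuting sample order within groups leaves posteriors unchanged
  fit2 <- suppressMessages(
    fit_two_group(expression_matrix(x, "count"), rev(apo), rev(sex)))
  expect_equal(fit2$table$PPDE, tab$PPDE, tolerance = 1e-10)

  # fixed-model monotonicity: pushing one group's total counts up never
  # decreases the posterior odds of differential expression
  r <- 10; sA <- 3; sB <- 3; alpha <- 1.2; beta <- 0.8; p <- 0.1
  ppde_fixed <- function(xa, xb) {
    lee <- beta_nb_logmarginal(c(xa, xb), r * c(sA, sB), alpha, beta)
    lde <- beta_nb_logmarginal(xa, r * sA, alpha, beta) +
      beta_nb_logmarginal(xb, r * sB, alpha, beta)
    1 / (1 + exp(log1p(-p) - log(p) + lee - lde))
  }
  for (xb in c(5, 30, 120)) {
    vals <- vapply(xb * 2^(0:6), ppde_fixed, numeric(1), xb = xb)
    expect_false(is.unsorted(vals))
  }

  # a transcript identical in every sample of both groups is never called
  same <- which(apply(x, 1, function(v) max(v) == min(v) & max(v) > 0))
  if (length(same))
    expect_true(all(tab$PPDE[same] < 0.95))
})

test_that("the mixture fraction is recovered on planted data", {
  set.seed(21)
  G <- 2000
  mu <- exp(runif(G, log(5), log(500)))
  de <- sample(G, G / 10)
  up <- de[seq_len(length(de) / 2)]; dn <- setdiff(de, up)
  mu2 <- matrix(rep(mu, 6), G, 6)
  mu2[up, 4:6] <- mu2[up, 4:6] * 4
  mu2[dn, 4:6] <- mu2[dn, 4:6] / 4
  y <- matrix(rnbinom(G * 6, mu = as.vector(mu2), size = 10), G, 6,
              dimnames = list(sprintf("t%04d", 1:G), paste0("s", 1:6)))
  fit <- fit_two_group(expression_matrix(y, "count"),
                       paste0("s", 1:3), paste0("s", 4:6))
  expect_lt(abs(fit$model$p_de - 0.1), 0.05)
})

test_that("soft posterior-FDR calls nest the hard-threshold calls", {
  ppde <- c(0.99, 0.97, 0.9, 0.6, NA, 0.2)
  calls <- ppde_fdr_calls(ppde, fdr = 0.05)
  expect_true(all(calls[c(1, 2)]))
  expect_false(any(calls[5:6]))
  # expected FDP of the call set stays at or below the target
  expect_lte(mean(1 - ppde[calls]), 0.05)
})
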