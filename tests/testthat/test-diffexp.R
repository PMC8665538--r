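test_that("maybe_log2 fires on linear intensities only", {
  lin <- withr::with_seed(1, matrix(stats::runif(60, 10, 20000), 10,
                                    dimnames = list(paste0("g", 1:10),
                                                    paste0("s", 1:6))))
  study <- expression_study(lin, rep(c("case", "control"), each = 3))
  out <- suppressMessages(maybe_log2(study))
  expect_equal(out$values, log2(lin + 1))

  logd <- expression_study(matrix(stats::runif(60, 2, 16), 10,
                                  dimnames = dimnames(lin)),
                           rep(c("case", "control"), each = 3))
  expect_identical(maybe_log2(logd), logd)

  neg <- lin; neg[1, 1] <- -3
  bad <- expression_study(neg, rep(c("case", "control"), each = 3))
  expect_error(maybe_log2(bad), "negative")
})

test_that("two-group fit reproduces hand pooled-variance arithmetic", {
  vals <- rbind(g1 = c(4, 6, 1, 3),
                g2 = c(5, 5, 5, 5),
                g3 = c(2, 2, 7, 7))
  colnames(vals) <- paste0("s", 1:4)
  # 2 samples per group: use the fit directly (I/O enforces >= 3)
  fit <- two_group_fit(structure(list(values = vals,
                                      genes = rownames(vals),
                                      samples = colnames(vals),
                                      groups = rep(c("case", "control"),
                                                   each = 2)),
                                 class = "expression_study"))
  expect_equal(fit$mean_diff, c(3, 0, -5))
  expect_equal(fit$s2[1], 2)       # pooled (2 + 2)/2
  expect_equal(fit$df_resid[1], 2)
  expect_equal(fit$s2[2], 0)       # constant gene passes through
})

test_that("prior estimation recovers simulated hyperparameters", {
  d0 <- 4; s0_sq <- 0.05; df <- 4
  s2 <- withr::with_seed(10, {
    sigma2 <- s0_sq * d0 / stats::rchisq(20000, df = d0)
    sigma2 * stats::rchisq(20000, df = df) / df
  })
  prior <- estimate_prior(s2, df)
  expect_lt(abs(prior$d0 - d0) / d0, 0.2)
  expect_lt(abs(prior$s0_sq - s0_sq) / s0_sq, 0.1)

  # zero excess dispersion collapses to an infinite-df prior
  expect_identical(estimate_prior(rep(2, 100), 4)$d0, Inf)

  # spread far beyond the trigamma bound still converges to a small d0
  wide <- withr::with_seed(11, exp(stats::rnorm(5000, 0, 4)))
  pw <- estimate_prior(wide, 10)
  expect_true(is.finite(pw$d0))
  expect_lt(pw$d0, 10)

  expect_error(estimate_prior(rep(0, 50), 4), "at least 10")
})

test_that("prior estimates agree with the limma cross-check", {
  s2 <- withr::with_seed(12, {
    sigma2 <- 0.1 * 5 / stats::rchisq(5000, df = 5)
    sigma2 * stats::rchisq(5000, df = 6) / 6
  })
  prior <- estimate_prior(s2, 6)
  lf <- limma::fitFDist(s2, df1 = 6)
  expect_equal(prior$d0, lf$df2, tolerance = 1e-6)
  expect_equal(prior$s0_sq, lf$scale, tolerance = 1e-6)
})

test_that("d0 = 0 reproduces the ordinary pooled t exactly", {
  study <- toy_study(n_genes = 40, n_case = 5, n_control = 5, seed = 13)
  fit <- two_group_fit(study)
  tab <- moderated_t(fit, structure(list(d0 = 0, s0_sq = 1),
                                    class = "ebayes_prior"))
  for (g in c("g01", "g17", "g33")) {
    i <- match(g, fit$gene)
    t_hand <- fit$mean_diff[i] / sqrt(fit$s2[i] * (1 / 5 + 1 / 5))
    expect_equal(tab$t_mod[match(g, tab$gene)], t_hand, tolerance = 1e-12)
    expect_equal(tab$df_total[match(g, tab$gene)], 8)
  }
})

test_that("moderated t matches limma's eBayes pipeline", {
  study <- toy_study(n_genes = 300, n_case = 6, n_control = 6, seed = 14)
  # heterogeneous gene variances so the fitted prior is finite
  sds <- withr::with_seed(14, sqrt(0.1 * 4 / stats::rchisq(300, df = 4)))
  study <- expression_study(study$values * sds, study$groups)
  tab <- run_diffexp(study)
  design <- cbind(1, as.integer(study$groups == "case"))
  lfit <- limma::eBayes(limma::lmFit(study$values, design))
  idx <- match(tab$gene, rownames(study$values))
  expect_equal(tab$t_mod, lfit$t[idx, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tab$p, lfit$p.value[idx, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("moderation rescues zero-variance genes", {
  vals <- withr::with_seed(15, matrix(stats::rnorm(200 * 10, 8, 1), 200,
                                      dimnames = list(sprintf("g%03d", 1:200),
                                                      paste0("s", 1:10))))
  vals[1, ] <- c(rep(9, 5), rep(8, 5)) # constant within groups, s2 = 0
  study <- expression_study(vals, rep(c("case", "control"), each = 5))
  tab <- run_diffexp(study)
  row <- tab[tab$gene == "g001", ]
  expect_true(is.finite(row$t_mod))
  expect_gt(abs(row$t_mod), 0)
})

test_that("|t_mod| is monotone in |mean_diff| and antitone in s2", {
  prior <- structure(list(d0 = 4, s0_sq = 0.05), class = "ebayes_prior")
  mk <- function(md, s2) data.frame(gene = "g", mean_diff = md, s2 = s2,
                                    df_resid = 8, n_case = 5, n_control = 5)
  t_at <- function(md, s2) abs(moderated_t(mk(md, s2), prior)$t_mod)
  expect_true(t_at(2, 1) > t_at(1, 1))
  expect_true(t_at(1, 0.5) > t_at(1, 2))
})

test_that("BH adjustment obeys the step-up definition and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(-0.1, 0.5)), "0, 1")

  p <- withr::with_seed(16, stats::runif(50))
  ord <- withr::with_seed(16, sample(50))
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
  # rejection set equals the classic step-up rule at level q
  q <- 0.1
  ps <- sort(p)
  k <- max(c(0, which(ps <= q * seq_along(ps) / length(ps))))
  classic <- if (k == 0) character(0) else which(p <= ps[k])
  expect_setequal(which(bh_adjust(p) <= q), classic)
})

test_that("planted expression shifts are detected with high power", {
  net <- generate_ppi(2000, 2, seed = 17)
  truth <- plant_modules(net, 1, 10, seed = 17)
  planted <- withr::with_seed(17, sample(net$nodes, 200))
  truth$planted_degs$D1 <- planted
  study <- generate_expression(net, truth, n_case = 8, n_control = 8,
                               delta = 2, seed = 17)
  tab <- run_diffexp(study)
  rate <- mean(tab$is_deg[match(planted, tab$gene)])
  expect_gt(rate, 0.9)
  # and the null genes stay mostly quiet under BH
  null_rate <- mean(tab$is_deg[!tab$gene %in% planted])
  expect_lt(null_rate, 0.05)
})
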