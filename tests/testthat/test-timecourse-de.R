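std_design <- function() simulate_counts(simulation_config(n_genes = 2,
                                                           seed = 1))$design

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # missing values are excluded from m and reinserted
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(-0.1), "\\[0, 1\\]")
})

test_that("BH output is monotone in p and never smaller than p", {
  set.seed(3)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("the NB IRLS fit matches independent GLM fits", {
  design <- std_design()
  s <- setNames(runif(16, 0.8, 1.2), design$sample)
  side_f <- factor(design$side)
  time_f <- factor(design$time)
  X <- model.matrix(~ side_f + time_f)
  set.seed(5)
  y <- rnbinom(16, mu = 60 * exp(rnorm(16, sd = 0.3)), size = 5)

  # alpha -> 0 reduces to the Poisson GLM
  ours <- fit_nb_glm(y, s, X, alpha = 0)
  ref <- glm(y ~ side_f + time_f, family = poisson(), offset = log(s))
  expect_true(ours$converged)
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)

  # fixed-dispersion NB against the classical negative.binomial family
  ours2 <- fit_nb_glm(y, s, X, alpha = 0.2, tol = 1e-10)
  ref2 <- glm(y ~ side_f + time_f,
              family = MASS::negative.binomial(theta = 1 / 0.2),
              offset = log(s), control = glm.control(epsilon = 1e-12))
  expect_equal(unname(ours2$coefficients), unname(coef(ref2)),
               tolerance = 1e-6)
})

test_that("the full model never fits worse than the reduced model", {
  sim <- simulate_counts(simulation_config(n_genes = 40, seed = 8))
  s <- size_factors(sim$counts)
  side_f <- factor(sim$design$side)
  time_f <- factor(sim$design$time)
  X_full <- model.matrix(~ side_f + time_f)
  X_red <- model.matrix(~ side_f)
  for (i in seq_len(nrow(sim$counts))) {
    y <- sim$counts[i, ]
    if (all(y == 0)) next
    f <- fit_nb_glm(y, s, X_full, alpha = 0.1)
    r <- fit_nb_glm(y, s, X_red, alpha = 0.1)
    if (f$converged && r$converged) {
      expect_gte(f$loglik, r$loglik - 1e-8)
      expect_lte(f$deviance, r$deviance + 1e-8)
    }
  }
})

test_that("reduced-model fitted means depend only on the side", {
  design <- std_design()
  s <- setNames(rep(1, 16), design$sample)
  X_red <- model.matrix(~ factor(design$side))
  set.seed(9)
  y <- rnbinom(16, mu = 50, size = 10)
  fit <- fit_nb_glm(y, s, X_red, alpha = 0.1)
  mu_by_side <- split(fit$fitted, design$side)
  for (v in mu_by_side) expect_equal(max(v) - min(v), 0, tolerance = 1e-8)
})

test_that("a constant gene yields a zero statistic and p = 1", {
  design <- std_design()
  counts <- rbind(gA = rep(7L, 16), gB = rep(c(3L, 9L), each = 8))
  colnames(counts) <- design$sample
  s <- setNames(rep(1, 16), design$sample)
  res <- lrt_time_effect(counts, s, design, dispersions = c(0.1, 0.1))
  expect_equal(res$lrt_stat[1], 0, tolerance = 1e-6)
  expect_equal(res$pvalue[1], 1, tolerance = 1e-6)
  expect_identical(res$df[res$tested][1], 3L)
})

test_that("all-zero genes are excluded and reported untested", {
  design <- std_design()
  counts <- rbind(gA = rep(0L, 16), gB = rep(5L, 16),
                  gC = rpois(16, 30))
  colnames(counts) <- design$sample
  s <- setNames(rep(1, 16), design$sample)
  res <- lrt_time_effect(counts, s, design, dispersions = rep(0.1, 3))
  expect_false(res$tested[1])
  expect_true(is.na(res$pvalue[1]))
  expect_false(res$de_flag[1])
  expect_true(all(res$tested[2:3]))
})

test_that("dispersion estimation floors at zero and recovers the truth", {
  design <- std_design()
  # within-cell variance below the mean -> alpha_raw = 0
  counts <- matrix(rep(c(10L, 10L), 16), nrow = 2,
                   dimnames = list(c("gA", "gB"), design$sample))
  counts[2, ] <- rep(c(40L, 42L), 8)
  s <- setNames(rep(1, 16), design$sample)
  d <- estimate_dispersions(counts, s, design)
  expect_equal(d$alpha_raw[1], 0)
  expect_true(all(d$alpha >= 0))

  # Poisson counts: small working dispersion at 2,000 genes
  cfg0 <- simulation_config(
    n_genes = 2000,
    class_proportions = c(null = 1, shared = 0, oral_specific = 0,
                          physa_specific = 0, complex = 0),
    dispersion_params = c(a0 = 0, a1 = 0), seed = 13)
  sim0 <- simulate_counts(cfg0)
  d0 <- estimate_dispersions(sim0$counts, size_factors(sim0$counts),
                             sim0$design)
  expect_lt(median(d0$alpha), 0.05)

  # true alpha = 0.2 recovered within a factor of two
  cfg2 <- simulation_config(
    n_genes = 2000,
    class_proportions = c(null = 1, shared = 0, oral_specific = 0,
                          physa_specific = 0, complex = 0),
    dispersion_params = c(a0 = 0.2, a1 = 0), seed = 14)
  sim2 <- simulate_counts(cfg2)
  d2 <- estimate_dispersions(sim2$counts, size_factors(sim2$counts),
                             sim2$design)
  expect_gt(median(d2$alpha), 0.1)
  expect_lt(median(d2$alpha), 0.4)

  # no replicated cell -> dispersion unidentifiable
  one_rep <- design[design$replicate == 1, ]
  expect_error(
    estimate_dispersions(counts[, one_rep$sample], s[one_rep$sample],
                         one_rep),
    "replicate")
})

test_that("planted time effects are detected with high power", {
  ds <- standard_dataset()
  cls <- ds$sim$truth$class
  shared <- cls == "shared"
  expect_gt(mean(ds$de$de_flag[shared]), 0.9)
})
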