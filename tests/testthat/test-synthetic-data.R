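test_that("configuration invariants are enforced with the field named", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(time_points = c(0, 8, 8)), "time_points")
  expect_error(simulation_config(time_points = c(8, 24)), "time_points")
  expect_error(simulation_config(class_proportions = c(
    null = 0.5, shared = 0.5, oral_specific = 0.2,
    physa_specific = 0, complex = 0)), "class_proportions")
  expect_error(simulation_config(size_factor_range = c(2, 1)),
               "size_factor_range")
  expect_error(simulation_config(dispersion_params = c(a0 = -1, a1 = 0)),
               "dispersion_params")
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- simulation_config(n_genes = 200, seed = 3)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_counts(simulation_config(n_genes = 200, seed = 4))
  expect_false(identical(a$counts, c_$counts))
})

test_that("class composition follows largest-remainder apportionment", {
  cfg <- simulation_config(n_genes = 10, seed = 1)
  sim <- simulate_counts(cfg)
  tab <- table(sim$truth$class)
  # exact shares (6, 2, .8, .8, .4): remainders put the 2 leftover genes
  # on the side-specific classes
  expect_equal(unname(tab[c("null", "shared", "oral_specific",
                            "physa_specific")]),
               c(6L, 2L, 1L, 1L), ignore_attr = TRUE)
  expect_false("complex" %in% names(tab))
  # composition within one gene of the requested share at larger n
  sim2 <- simulate_counts(simulation_config(n_genes = 997, seed = 1))
  tab2 <- table(sim2$truth$class)
  expect_true(all(abs(tab2 - 997 * simulation_config()$class_proportions[names(tab2)]) <= 1))
})

test_that("planted classes have the promised trajectory structure", {
  sim <- simulate_counts(simulation_config(n_genes = 500, seed = 5))
  tm <- sim$truth$true_means
  cls <- sim$truth$class
  flat <- function(m) apply(m, 1, function(v) max(v) - min(v)) == 0
  expect_true(all(flat(tm[cls == "null", "oral", ])))
  expect_true(all(flat(tm[cls == "null", "physa", ])))
  expect_equal(tm[cls == "shared", "oral", ], tm[cls == "shared", "physa", ])
  expect_true(all(flat(tm[cls == "oral_specific", "physa", ])))
  expect_false(any(flat(tm[cls == "oral_specific", "oral", ])))
  # complex genes: mirrored log2 trajectories cross at the baseline
  cx_o <- log2(tm[cls == "complex", "oral", ] / tm[cls == "complex", "oral", 1])
  cx_p <- log2(tm[cls == "complex", "physa", ] / tm[cls == "complex", "physa", 1])
  expect_equal(cx_o, -cx_p)
})

test_that("zero dispersion reaches the Poisson limit (variance ~ mean)", {
  cfg <- simulation_config(
    n_genes = 400,
    class_proportions = c(null = 1, shared = 0, oral_specific = 0,
                          physa_specific = 0, complex = 0),
    baseline_log_mean_range = c(log(200), log(400)),
    dispersion_params = c(a0 = 0, a1 = 0),
    size_factor_range = c(1, 1), seed = 9)
  sim <- simulate_counts(cfg)
  ratio <- apply(sim$counts, 1, var) / rowMeans(sim$counts)
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.25)
})

test_that("simulated counts average to size_factor x true_mean", {
  # many iid genes at a common mean stand in for repeated draws of one gene
  cfg <- simulation_config(
    n_genes = 10000,
    class_proportions = c(null = 1, shared = 0, oral_specific = 0,
                          physa_specific = 0, complex = 0),
    baseline_log_mean_range = c(log(100), log(100)),
    dispersion_params = c(a0 = 0.1, a1 = 0), seed = 21)
  sim <- simulate_counts(cfg)
  expected <- 100 * sim$truth$size_factors
  observed <- colMeans(sim$counts)
  expect_true(all(abs(observed - expected) / expected < 0.05))
})

test_that("annotation generator plants and reports enriched terms", {
  sim <- simulate_counts(simulation_config(n_genes = 500, seed = 6))
  ann <- simulate_annotation(sim, n_terms = 10, enriched_term_fraction = 0.2,
                             seed = 2, term_size = 30)
  expect_length(ann$enriched_terms, 2L)
  expect_true(all(ann$enriched_terms %in% ann$map$term))
  expect_equal(length(unique(ann$map$term)), 10L)
  # identical seed reproduces the map
  ann2 <- simulate_annotation(sim, n_terms = 10, enriched_term_fraction = 0.2,
                              seed = 2, term_size = 30)
  expect_identical(ann, ann2)
  # no planted enrichment when the fraction is 0
  ann0 <- simulate_annotation(sim, n_terms = 5, enriched_term_fraction = 0,
                              seed = 2)
  expect_length(ann0$enriched_terms, 0L)
})

test_that("a term covering all genes has fold enrichment exactly 1", {
  sim <- simulate_counts(simulation_config(n_genes = 200, seed = 6))
  genes <- names(sim$truth$class)
  ann <- simulate_annotation(sim, n_terms = 1, enriched_term_fraction = 0,
                             seed = 1, term_size = length(genes))
  res <- enrich(genes[1:37], genes, ann$map)
  expect_equal(res$fold_enrichment, 1)
  expect_equal(res$pvalue, 1)
})
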