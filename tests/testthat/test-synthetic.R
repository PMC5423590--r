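test_that("planted generator is deterministic and hits block densities", {
  a <- generate_planted_network(500, 0.10, 0.80, 0.20, 0.40, seed = 21)
  b <- generate_planted_network(500, 0.10, 0.80, 0.20, 0.40, seed = 21)
  expect_identical(a$network$ties, b$network$ties)
  expect_identical(unclass(a$partition), unclass(b$partition))
  expect_equal(core_size(a$partition), 50L)

  st <- build_state(a$network, a$partition)
  # realized densities within 4 binomial standard errors of the target
  dens_core <- (st$d_core - st$v_core) / st$d_core
  expect_lt(abs(dens_core - 0.80), 4 * sqrt(0.8 * 0.2 / st$d_core))
  dens_peri <- st$v_periphery / st$d_periphery
  expect_lt(abs(dens_peri - 0.20), 4 * sqrt(0.2 * 0.8 / st$d_periphery))
  core <- unclass(a$partition)
  inter <- sum(a$network$ties[core, !core]) + sum(a$network$ties[!core, core])
  n_inter <- 2 * 50 * 450
  expect_lt(abs(inter / n_inter - 0.40), 4 * sqrt(0.4 * 0.6 / n_inter))
})

test_that("extreme densities give a perfect planted structure", {
  pl <- generate_planted_network(60, 0.2, 1, 0, 1, seed = 2)
  expect_equal(correlation_from_state(build_state(pl$network, pl$partition)),
               1.0)
})

test_that("undirected generation mirrors one draw per pair", {
  pl <- generate_planted_network(80, 0.15, 0.7, 0.3, 0.6, directed = FALSE,
                                 seed = 9)
  expect_false(pl$network$directed)
  expect_identical(pl$network$ties, t(pl$network$ties))
})

test_that("core size is rounded half-up and bounds are enforced", {
  expect_equal(core_size(generate_planted_network(50, 0.05, .8, .2, .4,
                                                  seed = 1)$partition), 3L)
  expect_equal(core_size(generate_planted_network(45, 0.1, .8, .2, .4,
                                                  seed = 1)$partition), 5L)
  expect_error(generate_planted_network(20, 0.02, .8, .2, .4), "at least 2")
  expect_error(generate_planted_network(20, 0.5, 1.2, .2, .4), "\\[0, 1\\]")
  expect_error(generate_planted_network(3, 0.5, .8, .2, .4), "at least 4")
})

test_that("the crossed design enumerates every cell with stable seeds", {
  d <- benchmark_design()
  expect_equal(nrow(d), 72L)
  expect_equal(nrow(unique(d[, c("n", "core_fraction", "p_core",
                                 "p_periphery", "p_between")])), 72L)
  d3 <- benchmark_design(replicates = 3)
  expect_equal(nrow(d3), 216L)
  expect_identical(benchmark_design(base_seed = 5)$seed,
                   benchmark_design(base_seed = 5)$seed)
})

test_that("benchmark deviations are zero under self-reference", {
  d <- benchmark_design(n = 60, core_fraction = 0.2, p_core = 0.8,
                        p_periphery = 0.2, p_between = 0.4)
  res <- run_benchmark(d, budgets = 2000, reference_budget = 2000)
  expect_equal(res$deviation_raw, 0)
  expect_equal(res$deviation_pct, 0)
  expect_true(all(res$matched))
  s <- benchmark_summary(res)
  ov <- s[s$feature == "overall", ]
  expect_equal(ov$mrcd, 0)
  expect_equal(ov$mpcd, 0)
  expect_equal(ov$mpbf, 100)
})

test_that("shared-prefix budgets make best-found monotone in xi", {
  d <- benchmark_design(n = 60, core_fraction = c(0.1, 0.2), p_core = 0.8,
                        p_periphery = 0.2, p_between = c(0.4, 0.6))
  res <- run_benchmark(d, budgets = c(300, 3000), reference_budget = 3000)
  for (pb in split(res, res$problem)) {
    expect_lte(pb$r[pb$budget == 300], pb$r[pb$budget == 3000])
    expect_gte(min(pb$deviation_raw), 0)
  }
  s <- benchmark_summary(res)
  ov <- s[s$feature == "overall", ]
  expect_gte(ov$mrcd[ov$budget == 300], ov$mrcd[ov$budget == 3000])
  expect_gte(ov$mpbf[ov$budget == 3000], ov$mpbf[ov$budget == 300])
  expect_error(run_benchmark(d, budgets = 5000, reference_budget = 3000),
               "reference_budget")
  expect_error(run_benchmark(d[0, ], budgets = 100, reference_budget = 100),
               "non-empty")
})
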