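test_that("dyad counts follow k^2 - k per block", {
  expect_equal(dyad_counts(6, 14), list(d_core = 30L, d_periphery = 182L,
                                        d = 212L))
  expect_equal(dyad_counts(1, 19), list(d_core = 0L, d_periphery = 342L,
                                        d = 342L))
  expect_equal(dyad_counts(2, 2), list(d_core = 2L, d_periphery = 2L,
                                       d = 4L))
  expect_error(dyad_counts(-1, 5), "non-negative")
  expect_error(dyad_counts(1, 0), "at least 2")
})

test_that("network construction validates ties, symmetry and labels", {
  A <- matrix(0L, 4, 4); A[1, 2] <- 1L
  expect_error(binary_network(A, directed = FALSE), "asymmetric")
  A[2, 1] <- 1L
  expect_silent(binary_network(A, directed = FALSE))
  A[1, 2] <- 2L
  expect_error(binary_network(A), "0 or 1")
  expect_error(binary_network(matrix(0L, 3, 4)), "square")
  expect_error(binary_network(matrix(0L, 3, 3), labels = c("a", "a", "b")),
               "unique")
  # diagonal is ignored whatever it holds
  B <- matrix(1L, 3, 3); diag(B) <- 5L
  expect_equal(diag(binary_network(B)$ties), c(0L, 0L, 0L))
})

test_that("violation counts match extreme cases and pairwise enumeration", {
  full <- binary_network(matrix(1L, 7, 7) - diag(7L))
  empty <- binary_network(matrix(0L, 7, 7))
  part <- cp_partition(c(rep(TRUE, 3), rep(FALSE, 4)))
  expect_equal(count_violations(full, part),
               list(v_core = 0L, v_periphery = 12L))   # v_P = d_P
  expect_equal(count_violations(empty, part),
               list(v_core = 6L, v_periphery = 0L))    # v_C = d_C
  for (s in 1:5) {
    net <- random_network(6, p = 0.5, seed = s)
    for (split in list(1:3, c(1, 4, 6), 2:4)) {
      p <- cp_partition(seq_len(6) %in% split)
      expect_equal(count_violations(net, p), brute_violations(net, p))
    }
  }
  expect_error(count_violations(full, cp_partition(c(TRUE, FALSE))),
               "partition has")
})

test_that("build_state satisfies the state invariants", {
  for (s in 1:10) {
    net <- random_network(12, p = 0.35, seed = s, directed = s %% 2 == 0)
    part <- random_partition(12, seed = 100 + s)
    st <- build_state(net, part)
    nC <- core_size(part)
    expect_identical(st$n_core, nC)
    expect_identical(st$n_periphery, 12L - nC)
    expect_identical(st$d_core, nC * nC - nC)
    expect_identical(st$d, st$d_core + st$d_periphery)
    bv <- brute_violations(net, part)
    expect_identical(st$v_core, bv$v_core)
    expect_identical(st$v_periphery, bv$v_periphery)
    expect_true(st$v_core >= 0L && st$v_core <= st$d_core)
    expect_true(st$v_periphery >= 0L && st$v_periphery <= st$d_periphery)
  }
  net <- random_network(5, seed = 1)
  all_core <- build_state(net, cp_partition(rep(TRUE, 5)))
  expect_equal(all_core[c("n_periphery", "d_periphery", "v_periphery")],
               list(n_periphery = 0L, d_periphery = 0L, v_periphery = 0L))
  all_peri <- build_state(net, cp_partition(rep(FALSE, 5)))
  expect_equal(all_peri[c("n_core", "d_core", "v_core")],
               list(n_core = 0L, d_core = 0L, v_core = 0L))
})

test_that("closed-form correlation reproduces the published worked example", {
  cmp <- correlation_components(cp_state(6, 14, 2, 8))
  expect_equal(round(cmp$s2_ideal, 6), 0.121485)
  expect_equal(round(cmp$s2_observed, 6), 0.140975)
  expect_equal(round(cmp$covariance, 6), 0.108046)
  expect_equal(round(cmp$r, 5), 0.82561)
})

test_that("correlation hits its bounds and degenerates to NA", {
  # zero violations: observed equals ideal
  expect_equal(correlation_from_state(cp_state(4, 6, 0, 0)), 1.0)
  # maximal violations: observed is the ideal inverted
  expect_equal(correlation_from_state(cp_state(4, 6, 12, 30)), -1.0)
  # singleton core: d_C = 0 so the ideal vector is constant
  expect_true(is.na(correlation_from_state(cp_state(1, 9, 0, 5))))
  # constant observed vector: complete network
  expect_true(is.na(correlation_from_state(cp_state(4, 6, 0, 30))))
  # defined values stay within [-1, 1]
  for (s in 1:50) {
    set.seed(s)
    st <- build_state(random_network(9, p = runif(1, .1, .9)),
                      random_partition(9))
    r <- correlation_from_state(st)
    if (!is.na(r)) expect_true(r >= -1 && r <= 1)
  }
})

test_that("incremental move evaluation equals scratch recomputation", {
  for (s in 1:50) {
    n <- sample(5:15, 1)
    net <- random_network(n, p = runif(1, .2, .7), seed = 7000 + s,
                          directed = s %% 2 == 0)
    part <- random_partition(n, seed = 8000 + s)
    st <- build_state(net, part)
    h <- sample(n, 1)
    inc <- evaluate_move(st, net, part, h)
    expect_equal(inc, build_state(net, flip_actor(part, h)))
  }
})

test_that("evaluate_move is an involution and handles boundary blocks", {
  net <- random_network(8, seed = 42)
  part <- random_partition(8, seed = 43)
  st <- build_state(net, part)
  h <- 3
  back <- evaluate_move(evaluate_move(st, net, part, h), net,
                        flip_actor(part, h), h)
  expect_equal(back, st)
  # moving the sole core actor empties the core
  solo <- cp_partition(seq_len(8) == 2)
  out <- evaluate_move(build_state(net, solo), net, solo, 2)
  expect_identical(out$n_core, 0L)
  expect_identical(out$v_core, 0L)
  expect_error(evaluate_move(st, net, part, 9), "actor index")
})

test_that("a long random flip sequence keeps the state exact", {
  net <- random_network(20, p = 0.4, seed = 99)
  part <- random_partition(20, seed = 100)
  st <- build_state(net, part)
  set.seed(101)
  for (k in 1:1000) {
    h <- sample(20, 1)
    st <- evaluate_move(st, net, part, h)
    part <- flip_actor(part, h)
  }
  expect_identical(unclass(st), unclass(build_state(net, part)))
})

test_that("relabeling actors leaves the correlation unchanged", {
  for (s in 1:10) {
    n <- 11
    net <- random_network(n, p = 0.45, seed = 300 + s)
    part <- random_partition(n, seed = 400 + s)
    perm <- sample(n)
    pnet <- binary_network(net$ties[perm, perm])
    ppart <- cp_partition(unclass(part)[perm])
    expect_equal(correlation_from_state(build_state(net, part)),
                 correlation_from_state(build_state(pnet, ppart)))
  }
})
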