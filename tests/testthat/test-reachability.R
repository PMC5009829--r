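test_that("diagram construction finds the attractor cycles", {
  d <- build_diagram(transition_matrix(p53_network()))
  expect_length(d$cycles, 1)
  expect_true(same_cycle(d$cycles[[1]],
                         c(8L, 4L, 2L, 10L, 13L, 15L)))
  d1 <- build_diagram(transition_matrix_from_successor(c(3, 1, 4, 2)))
  expect_length(d1$cycles, 1)
  expect_length(d1$cycles[[1]], 4)
  ident <- build_diagram(transition_matrix_from_successor(1:8))
  expect_length(ident$cycles, 8)
  expect_true(all(lengths(ident$cycles) == 1))
})

test_that("basins map every state to its attractor", {
  d <- build_diagram(eight_state_fixture())
  expect_length(d$cycles, 1)
  expect_true(all(d$basin == 1L))
  two_fp <- build_diagram(transition_matrix_from_successor(c(1, 2)))
  expect_equal(two_fp$basin, c(1L, 2L))
})

test_that("the reachability test recognizes full-cycle permutations", {
  for (succ in printed_two_node_forms()) {
    expect_true(is_reachable_network(transition_matrix_from_successor(succ)))
  }
  expect_false(is_reachable_network(transition_matrix(p53_network())))
  expect_false(is_reachable_network(transition_matrix_from_successor(1:4)))
})

test_that("state classification matches the worked examples", {
  rep_p53 <- classify_states(transition_matrix(p53_network()))
  expect_false(rep_p53$network_reachable)
  expect_equal(rep_p53$reachable_states, c(2L, 4L, 8L, 10L, 13L, 15L))
  expect_equal(rep_p53$non_reachable_states,
               setdiff(1:16, c(2, 4, 8, 10, 13, 15)))

  rep8 <- classify_states(eight_state_fixture())
  expect_equal(rep8$non_reachable_states, c(1L, 2L, 6L))
  expect_equal(rep8$reachable_states, c(3L, 4L, 5L, 7L, 8L))

  # two attractors: nothing is reachable from every initial state
  rep_fp <- classify_states(transition_matrix(boolean_network(c(x1 = "x1"))))
  expect_length(rep_fp$reachable_states, 0)
  expect_equal(rep_fp$non_reachable_states, c(1L, 2L))
})

test_that("matrix property checks behave per definition", {
  ck <- check_matrix_properties(transition_matrix_from_successor(c(3, 1, 4, 2)))
  expect_true(ck$permutation && ck$zero_diagonal && ck$no_two_cycles)
  ck_id <- check_matrix_properties(transition_matrix_from_successor(1:4))
  expect_false(ck_id$zero_diagonal)
  ck_two <- check_matrix_properties(transition_matrix_from_successor(c(2, 1, 4, 3)))
  expect_true(ck_two$permutation && ck_two$zero_diagonal)
  expect_false(ck_two$no_two_cycles)
  # the 1-node exception: the unique reachable network is itself a 2-cycle
  ck1 <- check_matrix_properties(transition_matrix_from_successor(c(2, 1)))
  expect_true(is.na(ck1$no_two_cycles))
  expect_true(is_reachable_network(transition_matrix_from_successor(c(2, 1))))
})

test_that("reachability, property checks and classification coincide (n = 2, exhaustive)", {
  grid <- expand.grid(1:4, 1:4, 1:4, 1:4)
  for (r in seq_len(nrow(grid))) {
    succ <- as.integer(grid[r, ])
    L <- transition_matrix_from_successor(succ)
    reach <- is_reachable_network(L)
    ck <- check_matrix_properties(L)
    d <- build_diagram(L)
    single_orbit <- length(d$cycles) == 1L && length(d$cycles[[1]]) == 4L
    expect_equal(reach,
                 isTRUE(ck$permutation) && isTRUE(ck$zero_diagonal) &&
                   isTRUE(ck$no_two_cycles) && single_orbit)
    expect_equal(reach,
                 length(classify_states(L)$reachable_states) == 4L)
  }
})

test_that("classification is invariant under state relabeling", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    d <- 2L^n
    L <- random_transition_matrix(n)
    sigma <- sample.int(d)
    conj <- integer(d)
    conj[sigma] <- sigma[L$successor]
    a <- classify_states(L)
    b <- classify_states(transition_matrix_from_successor(conj))
    expect_equal(sort(sigma[a$reachable_states]), b$reachable_states)
    expect_equal(a$network_reachable, b$network_reachable)
    expect_equal(length(a$attractors), length(b$attractors))
  }
})

test_that("trajectories enter a cycle within 2^n steps", {
  set.seed(59)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    L <- random_transition_matrix(n)
    traj <- simulate_network(L, initial = sample.int(2L^n, 1))
    expect_false(is.na(traj$period))
    expect_lte(length(traj$transient), 2L^n - traj$period)
  }
})

test_that("DOT export has one edge per state and styles the reachable set", {
  dot <- export_dot(build_diagram(transition_matrix_from_successor(c(3, 1, 4, 2))))
  expect_equal(length(gregexpr("->", dot, fixed = TRUE)[[1]]), 4L)
  expect_equal(length(gregexpr("fontcolor=red", dot)[[1]]), 4L)

  p53_dot <- export_dot(build_diagram(transition_matrix(p53_network())))
  expect_equal(length(gregexpr("->", p53_dot, fixed = TRUE)[[1]]), 16L)
  expect_equal(length(gregexpr("fontcolor=red", p53_dot)[[1]]), 6L)
  expect_equal(length(gregexpr("fontcolor=blue", p53_dot)[[1]]), 10L)

  set.seed(61)
  for (rep in 1:5) {
    n <- sample(1:3, 1)
    L <- random_transition_matrix(n)
    dot <- export_dot(build_diagram(L))
    expect_equal(length(gregexpr("->", dot, fixed = TRUE)[[1]]), 2L^n)
  }
})
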