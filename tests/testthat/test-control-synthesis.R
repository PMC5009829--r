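L1 <- transition_matrix_from_successor(c(3, 1, 4, 2))
base2 <- boolean_network(c(x1 = "!x2", x2 = "x1"))

test_that("the dummy operator discards the second STP factor", {
  E <- as.matrix(dummy_operator())
  expect_equal(E, rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)))
  for (a in 0:1) {
    for (b in 0:1) {
      expect_equal(stp_chain(E, boolean_vector(a), boolean_vector(b)),
                   boolean_vector(a))
    }
  }
})

test_that("lifting a structure matrix ignores the appended variable", {
  M1 <- logical_matrix(c(2, 1, 2, 1), rows = 2)  # !x2 over (x1, x2)
  lifted <- lift_structure_matrix(M1)
  expect_equal(dim(lifted), c(2L, 8L))
  # top row over the 8 extended states: !x2 evaluated at every (x1,x2,x3)
  vars3 <- c("x1", "x2", "x3")
  expect_equal(2L - lifted$col_index,
               truth_table(parse_expression("!x2", vars3), vars3))
  # extended column (j, x3) equals base column j
  expect_equal(lifted$col_index, rep(M1$col_index, each = 2))
  # constant-true lifts to constant-true
  ct <- lift_structure_matrix(logical_matrix(rep(1, 4), rows = 2))
  expect_equal(ct$col_index, rep(1L, 8))
  expect_error(lift_structure_matrix(logical_matrix(1:3, rows = 4)), "2 rows")
})

test_that("block doubling follows the identity/skew rule", {
  ext <- extend_transition_matrix(
    L1, c("identity", "identity", "identity", "skew"))
  expect_equal(ext$successor, c(5L, 6L, 1L, 2L, 7L, 8L, 4L, 3L))
  d <- build_diagram(ext)
  expect_length(d$cycles, 1)
  expect_true(same_cycle(d$cycles[[1]], c(1L, 5L, 7L, 4L, 2L, 6L, 8L, 3L)))

  all_id <- extend_transition_matrix(L1, rep("identity", 4))
  d2 <- build_diagram(all_id)
  expect_length(d2$cycles, 2)
  expect_true(all(lengths(d2$cycles) == 4))
  expect_false(is_reachable_network(all_id))

  expect_error(extend_transition_matrix(L1, rep("identity", 3)),
               "one entry per 1-block")
})

test_that("block collapse inverts any extension", {
  set.seed(73)
  for (rep in 1:20) {
    n <- sample(1:3, 1)
    L <- random_transition_matrix(n)
    asn <- sample(c("identity", "skew"), 2L^n, replace = TRUE)
    ext <- extend_transition_matrix(L, asn)
    expect_equal(collapse_transition_matrix(ext)$successor, L$successor)
  }
})

test_that("an extension of a reachable base is reachable iff skew parity is odd", {
  asns <- expand.grid(rep(list(c("identity", "skew")), 4),
                      stringsAsFactors = FALSE)
  n_reachable <- 0L
  for (r in seq_len(nrow(asns))) {
    asn <- unlist(asns[r, ])
    predicted <- is_extension_reachable(asn, L1)
    actual <- is_reachable_network(extend_transition_matrix(L1, asn))
    expect_equal(predicted, actual)
    n_reachable <- n_reachable + actual
  }
  expect_equal(n_reachable, 8L)

  # sampled parity checks on 3-node reachable bases
  set.seed(79)
  for (rep in 1:15) {
    L <- random_full_cycle_matrix(3)
    asn <- sample(c("identity", "skew"), 8, replace = TRUE)
    expect_equal(is_extension_reachable(asn, L),
                 is_reachable_network(extend_transition_matrix(L, asn)))
  }

  expect_error(is_extension_reachable(rep("skew", 4),
                                      transition_matrix_from_successor(1:4)),
               "must itself be reachable")
})

test_that("synthesized feedback law matches the worked three-node example", {
  law <- synthesize_feedback_control(base2, "x3")
  vars3 <- c("x1", "x2", "x3")
  printed_u <- parse_expression("(!x1 & !x2 & !x3) | (x1 & x3) | (x2 & x3)",
                                vars3)
  expect_equal(truth_table(law$u, vars3), truth_table(printed_u, vars3))
  expect_equal(law$L$successor, c(5L, 6L, 1L, 2L, 7L, 8L, 4L, 3L))
  expect_true(is_reachable_network(law$L))
  expect_equal(law$lifted_structure_matrix$col_index,
               2L - truth_table(printed_u, vars3))
})

test_that("every odd-skew assignment yields a reachable closed loop", {
  asns <- expand.grid(rep(list(c("identity", "skew")), 4),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(asns))) {
    asn <- unlist(asns[r, ])
    if (sum(asn == "skew") %% 2L == 1L) {
      law <- synthesize_feedback_control(base2, "x3", asn)
      expect_true(is_reachable_network(law$L))
      expect_equal(law$L$successor,
                   extend_transition_matrix(transition_matrix(base2),
                                            asn)$successor)
    } else {
      expect_error(synthesize_feedback_control(base2, "x3", asn),
                   "odd number of skew")
    }
  }
})

test_that("chained extensions keep the network reachable", {
  law3 <- synthesize_feedback_control(base2, "x3")
  law4 <- synthesize_feedback_control(law3$closed_loop, "x4")
  d <- build_diagram(law4$L)
  expect_length(d$cycles, 1)
  expect_length(d$cycles[[1]], 16)
})
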