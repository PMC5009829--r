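vars2 <- c("x1", "x2")
vars3 <- c("x1", "x2", "x3")

test_that("parser handles precedence, aliases and round trips", {
  e <- parse_expression("!x2", vars2)
  expect_equal(truth_table(e, vars2), c(0L, 1L, 0L, 1L))
  # precedence: ! > & > | > xor family
  e2 <- parse_expression("!x1 & x2 | x1", vars2)
  expect_equal(truth_table(e2, vars2),
               truth_table(parse_expression("((!x1) & x2) | x1", vars2),
                           vars2))
  # unicode synonyms
  e3 <- parse_expression("¬ x1 ∧ x2", vars2)
  expect_equal(truth_table(e3, vars2),
               truth_table(parse_expression("!x1 & x2", vars2), vars2))
  # serialize-parse round trip preserves semantics
  set.seed(5)
  for (rep in 1:20) {
    tab <- sample(0:1, 8, replace = TRUE)
    e <- minimize_to_sop(tab, vars3)
    txt <- deparse_expression(e)
    expect_equal(truth_table(parse_expression(txt, vars3), vars3), tab)
  }
})

test_that("parser reports position-bearing errors", {
  expect_error(parse_expression("x1 &", vars2), "end of expression")
  expect_error(parse_expression("x1 & y9", vars2), "undeclared symbol 'y9'")
  expect_error(parse_expression("(x1 & x2", vars2), "\\)")
  expect_error(parse_expression("x1 @ x2", vars2), "position")
})

test_that("self-exclusive-or is constantly false", {
  e <- parse_expression("x1 ^ x1", vars2)
  expect_equal(truth_table(e, vars2), rep(0L, 4))
})

test_that("truth tables follow integrated-state order", {
  conj <- parse_expression("x1 & x2", vars2)
  expect_equal(truth_table(conj, vars2), c(1L, 0L, 0L, 0L))
  expect_equal(truth_table(parse_expression("1", vars2), vars2), rep(1L, 4))
  u <- parse_expression("(!x1 & !x2 & !x3) | (x1 & x3) | (x2 & x3)", vars3)
  expect_equal(truth_table(u, vars3), c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 1L))
})

test_that("structure matrices of the 16 two-variable operators are correct", {
  ops <- list(
    "1"             = c(1L, 1L, 1L, 1L),
    "0"             = c(2L, 2L, 2L, 2L),
    "x1"            = c(1L, 1L, 2L, 2L),
    "x2"            = c(1L, 2L, 1L, 2L),
    "!x1"           = c(2L, 2L, 1L, 1L),
    "!x2"           = c(2L, 1L, 2L, 1L),
    "x1 & x2"       = c(1L, 2L, 2L, 2L),
    "x1 | x2"       = c(1L, 1L, 1L, 2L),
    "x1 <- x2"      = c(1L, 1L, 2L, 1L),
    "x1 -> x2"      = c(1L, 2L, 1L, 1L),
    "!(x1 <- x2)"   = c(2L, 2L, 1L, 2L),
    "!(x1 -> x2)"   = c(2L, 1L, 2L, 2L),
    "x1 <-> x2"     = c(1L, 2L, 2L, 1L),
    "x1 nand x2"    = c(2L, 1L, 1L, 1L),
    "x1 nor x2"     = c(2L, 2L, 2L, 1L),
    "x1 ^ x2"       = c(2L, 1L, 1L, 2L))
  seen <- character()
  for (txt in names(ops)) {
    M <- structure_matrix(parse_expression(txt, vars2), vars2)
    expect_equal(M$col_index, ops[[txt]], label = txt)
    seen <- c(seen, paste(M$col_index, collapse = ""))
  }
  # pairwise distinct and exhausting all 2^4 logical 2x4 matrices
  expect_equal(length(unique(seen)), 16L)
  all16 <- apply(expand.grid(1:2, 1:2, 1:2, 1:2), 1, paste, collapse = "")
  expect_setequal(seen, all16)
})

test_that("structure matrix acts correctly on encoded states", {
  set.seed(9)
  for (rep in 1:10) {
    tab <- sample(0:1, 8, replace = TRUE)
    e <- minimize_to_sop(tab, vars3)
    M <- as.matrix(structure_matrix(e, vars3))
    for (j in 1:8) {
      bits <- decode_state(j, 3)
      x <- Reduce(stp, lapply(bits, boolean_vector))
      expect_equal(stp(M, x), boolean_vector(tab[j]))
    }
  }
})

test_that("minimization is exact, canonical and semantics-preserving", {
  expect_equal(deparse_expression(minimize_to_sop(c(0, 1, 0, 1), vars2)),
               "!x2")
  expect_equal(deparse_expression(minimize_to_sop(rep(0, 4), vars2)), "0")
  expect_equal(deparse_expression(minimize_to_sop(rep(1, 8), vars3)), "1")
  count_literals <- function(e) {
    e <- unclass(e)
    switch(e$op, const = 0L, var = 1L, not = count_literals(e$arg),
           count_literals(e$lhs) + count_literals(e$rhs))
  }
  set.seed(17)
  for (rep in 1:50) {
    tab <- sample(0:1, 8, replace = TRUE)
    e <- minimize_to_sop(tab, vars3)
    expect_equal(truth_table(e, vars3), tab)
    raw <- parse_expression(minterm_expression(tab, vars3), vars3)
    expect_lte(count_literals(e), max(count_literals(raw), 1L))
  }
})

test_that("minimization round trips through structure matrices (k <= 3)", {
  for (k in 1:3) {
    vars <- paste0("x", seq_len(k))
    tabs <- expand.grid(rep(list(0:1), 2L^k))
    for (r in seq_len(nrow(tabs))) {
      tab <- as.integer(tabs[r, ])
      e <- minimize_to_sop(tab, vars)
      expect_equal(structure_matrix(e, vars)$col_index, 2L - tab)
    }
  }
})
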