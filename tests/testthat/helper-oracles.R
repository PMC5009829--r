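# Independent oracles and fixture builders used across the suite.

# Semi-tensor product evaluated term by term from its definition, with the
# Kronecker expansions written out as explicit element loops (independent of
# base kronecker() and of stp()).
oracle_stp <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 1)
  if (!is.matrix(B)) B <- matrix(B, ncol = 1)
  n <- ncol(A); p <- nrow(B)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a <- n / g(n, p) * p
  kron_id <- function(M, k) {
    # M (r x c) Kronecker identity of size k, by explicit placement
    out <- matrix(0, nrow(M) * k, ncol(M) * k)
    for (i in seq_len(nrow(M))) {
      for (j in seq_len(ncol(M))) {
        for (s in seq_len(k)) {
          out[(i - 1) * k + s, (j - 1) * k + s] <- M[i, j]
        }
      }
    }
    out
  }
  kron_id(A, a / n) %*% kron_id(B, a / p)
}

# Successor map computed by plain truth-table iteration over per-node update
# functions given as R functions of the bit vector (independent of the
# package's expression machinery).
oracle_successor <- function(update_funs, n) {
  vapply(seq_len(2L^n), function(j) {
    bits <- bnreach::decode_state(j, n)
    nxt <- vapply(update_funs, function(f) f(bits), integer(1))
    bnreach::encode_state(nxt)
  }, integer(1))
}

# Build an unminimized sum-of-minterms expression string for a truth table
# (all-ones-first row order); used to make large random networks cheaply.
minterm_expression <- function(table, vars) {
  ones <- which(table == 1L)
  if (length(ones) == 0L) return("0")
  terms <- vapply(ones, function(j) {
    bits <- bnreach::decode_state(j, length(vars))
    lits <- ifelse(bits == 1L, vars, paste0("!", vars))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

random_sop_network <- function(n) {
  vars <- paste0("x", seq_len(n))
  updates <- vapply(seq_len(n), function(i) {
    minterm_expression(sample(c(0L, 1L), 2L^n, replace = TRUE), vars)
  }, character(1))
  names(updates) <- vars
  bnreach::boolean_network(updates)
}

# Are two integer vectors equal up to cyclic rotation?
same_cycle <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  k <- match(b[1], a)
  if (is.na(k)) return(FALSE)
  rot <- c(a[k:length(a)], if (k > 1) a[1:(k - 1)])
  identical(as.integer(rot), as.integer(b))
}

# Worked 8-state fixture: unique attractor cycle 3->5->7->8->4->3
# with states 1, 2, 6 feeding into it.
eight_state_fixture <- function() {
  bnreach::transition_matrix_from_successor(c(3L, 5L, 5L, 3L, 7L, 8L, 8L, 4L))
}

# The six printed canonical 2-node transition matrices, as successor tuples.
printed_two_node_forms <- function() {
  list(c(3L, 1L, 4L, 2L), c(2L, 4L, 1L, 3L), c(4L, 1L, 2L, 3L),
       c(4L, 3L, 1L, 2L), c(2L, 3L, 4L, 1L), c(3L, 4L, 2L, 1L))
}
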