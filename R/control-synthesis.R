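#' Dummy operator matrix
#'
#' The fixed 2 x 4 logical matrix E that discards the second factor of an
#' STP product of Boolean vectors: E stp x stp y = x. Lifting a structure
#' matrix with E makes it ignore a newly appended variable.
#'
#' @return A [logical_matrix] (dense form `(1 1 0 0 / 0 0 1 1)`).
#' @export
dummy_operator <- function() {
  logical_matrix(c(1L, 1L, 2L, 2L), rows = 2L)
}

#' Lift a structure matrix to one more variable
#'
#' Given the 2 x 2^n structure matrix M of a Boolean function of n
#' variables, returns the 2 x 2^(n+1) matrix M* = E stp M computing the
#' same function on the extended state space, ignoring the appended
#' variable: the column for extended state (j, x_{n+1}) equals column j of
#' M.
#'
#' @param M a [logical_matrix] (or dense 2-row 0/1 matrix).
#' @return A [logical_matrix] with 2 rows and twice the columns.
#' @examples
#' M1 <- logical_matrix(c(2, 1, 2, 1), rows = 2)  # !x2 over (x1, x2)
#' as.matrix(lift_structure_matrix(M1))
#' @export
lift_structure_matrix <- function(M) {
  M <- if (inherits(M, "logical_matrix")) M else as_logical_matrix(M)
  if (M$rows != 2L) stop("`M` must have 2 rows (a structure matrix)")
  dense <- stp(as.matrix(dummy_operator()), as.matrix(M))
  as_logical_matrix(dense)
}

#' Extend a transition matrix by one node (block doubling)
#'
#' Each nonzero cell ("1-block") of the base n-node transition matrix —
#' cell (i, j) with i = successor of state j — is expanded into a 2 x 2
#' block of the (n+1)-node matrix: an identity block sends the two lifted
#' states (2j-1, 2j) to (2i-1, 2i); a skew (anti-diagonal) block sends them
#' to (2i, 2i-1). Collapsing the 2 x 2 blocks of the result recovers the
#' base matrix exactly. When the base is reachable, the extension is
#' reachable iff the number of skew blocks is odd.
#'
#' @param L_base a `transition_matrix` for n nodes.
#' @param assignment character vector of length 2^n with entries
#'   `"identity"` or `"skew"`; entry j chooses the block for the 1-block in
#'   column j of the base matrix.
#' @return A `transition_matrix` for n + 1 nodes.
#' @examples
#' L1 <- transition_matrix_from_successor(c(3, 1, 4, 2))
#' extend_transition_matrix(L1, c("identity", "identity", "identity", "skew"))
#' @export
extend_transition_matrix <- function(L_base, assignment) {
  L_base <- as_transition_matrix(L_base)
  d <- 2L^L_base$n
  assignment <- match.arg(as.character(assignment), c("identity", "skew"),
                          several.ok = TRUE)
  if (length(assignment) != d) {
    stop(sprintf("`assignment` must have one entry per 1-block (%d)", d))
  }
  succ <- integer(2L * d)
  for (j in seq_len(d)) {
    i <- L_base$successor[j]
    if (assignment[j] == "identity") {
      succ[2L * j - 1L] <- 2L * i - 1L
      succ[2L * j] <- 2L * i
    } else {
      succ[2L * j - 1L] <- 2L * i
      succ[2L * j] <- 2L * i - 1L
    }
  }
  new_transition_matrix(succ, L_base$n + 1L)
}

#' Collapse the 2 x 2 blocks of an extended transition matrix
#'
#' Inverse of the block-doubling construction: maps an (n+1)-node
#' transition matrix built by [extend_transition_matrix()] back to its
#' n-node base.
#'
#' @param L a `transition_matrix` for n + 1 nodes whose 2 x 2 blocks each
#'   contain the two 1s of one base 1-block.
#' @return A `transition_matrix` for n nodes.
#' @export
collapse_transition_matrix <- function(L) {
  L <- as_transition_matrix(L)
  if (L$n < 2L) stop("nothing to collapse for n < 2")
  d <- 2L^(L$n - 1L)
  succ <- integer(d)
  for (j in seq_len(d)) {
    i1 <- ceiling(L$successor[2L * j - 1L] / 2)
    i2 <- ceiling(L$successor[2L * j] / 2)
    if (i1 != i2) {
      stop("matrix does not have the 2 x 2 block-doubled structure")
    }
    succ[j] <- i1
  }
  new_transition_matrix(succ, L$n - 1L)
}

#' Parity test for a block-doubled extension
#'
#' For a reachable base (single 2^n-cycle), an extension is reachable —
#' a single 2^(n+1)-cycle — iff the assignment contains an odd number of
#' skew blocks: traversing the base cycle composes the 2 x 2 blocks, and
#' the two lifted sheets are exchanged iff the number of swaps is odd.
#'
#' @inheritParams extend_transition_matrix
#' @return `TRUE` or `FALSE`.
#' @export
is_extension_reachable <- function(assignment, L_base) {
  L_base <- as_transition_matrix(L_base)
  if (!is_reachable_network(L_base)) {
    stop("`L_base` must itself be reachable (a single full cycle)")
  }
  assignment <- match.arg(as.character(assignment), c("identity", "skew"),
                          several.ok = TRUE)
  if (length(assignment) != 2L^L_base$n) {
    stop("`assignment` must have one entry per 1-block")
  }
  sum(assignment == "skew") %% 2L == 1L
}

#' Synthesize a state-feedback control law for an appended node
#'
#' Given a reachable n-node base network and a new node driven by a control
#' input, constructs a feedback law u(x_1, ..., x_{n+1}) making the closed
#' (n+1)-node network reachable. The base transition matrix is lifted by
#' block doubling under the given assignment (which must have odd skew
#' parity); the new node's truth table is read off the lifted matrix and
#' minimized to sum-of-products form. The closed loop — base updates plus
#' the new node updated by u — has exactly the lifted transition matrix.
#'
#' The default assignment places a single skew block on the base 1-block
#' with the largest column index and identity blocks elsewhere.
#'
#' @param base a reachable closed `boolean_network` with n nodes.
#' @param new_node name for the appended node.
#' @param assignment `"default"` or a character vector as in
#'   [extend_transition_matrix()] with odd skew count.
#' @return An object of class `feedback_law` with fields `u` (the
#'   minimized `boolean_expr`), `lifted_structure_matrix` (the
#'   2 x 2^(n+1) logical matrix of u), `closed_loop` (the closed
#'   `boolean_network`) and `L` (its transition matrix, equal to the
#'   lifted matrix).
#' @examples
#' base <- boolean_network(c(x1 = "!x2", x2 = "x1"))
#' law <- synthesize_feedback_control(base, "x3")
#' law$u
#' @export
synthesize_feedback_control <- function(base, new_node,
                                        assignment = "default") {
  stopifnot(inherits(base, "boolean_network"))
  if (length(base$inputs) > 0L) {
    stop("`base` must be a closed network")
  }
  if (new_node %in% base$nodes) {
    stop(sprintf("'%s' is already a node of the base network", new_node))
  }
  L_base <- transition_matrix(base)
  if (!is_reachable_network(L_base)) {
    stop("`base` must be a reachable network (single full cycle)")
  }
  d <- 2L^L_base$n
  if (identical(assignment, "default")) {
    assignment <- c(rep("identity", d - 1L), "skew")
  }
  if (!is_extension_reachable(assignment, L_base)) {
    stop(paste("synthesis failure: the extension is reachable only when",
               "the assignment has an odd number of skew blocks"))
  }
  L_ext <- extend_transition_matrix(L_base, assignment)
  vars <- c(base$nodes, new_node)
  n1 <- L_ext$n
  # truth table of the appended node: last bit of each successor state
  u_table <- vapply(L_ext$successor, function(s) decode_state(s, n1)[n1],
                    integer(1))
  u <- minimize_to_sop(u_table, vars)
  updates <- c(
    vapply(base$nodes, function(nm) deparse_expression(base$updates[[nm]]),
           character(1)),
    stats::setNames(deparse_expression(u), new_node))
  names(updates)[seq_along(base$nodes)] <- base$nodes
  closed <- boolean_network(updates)
  L_closed <- transition_matrix(closed)
  if (!identical(L_closed$successor, L_ext$successor)) {
    stop("internal consistency failure: closed loop does not match lift")
  }
  structure(list(u = u,
                 lifted_structure_matrix = structure_matrix(u, vars),
                 closed_loop = closed,
                 L = L_closed,
                 assignment = assignment),
            class = "feedback_law")
}

#' @export
print.feedback_law <- function(x, ...) {
  cat("State-feedback control law\n")
  cat("  u =", deparse_expression(x$u), "\n")
  cat(sprintf("  closed loop (%d nodes) reachable: %s\n",
              length(x$closed_loop$nodes),
              if (is_reachable_network(x$L)) "yes" else "no"))
  invisible(x)
}
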