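#' Enumerate the six simplest reachable two-node networks
#'
#' Runs over all 2^4 x 2^4 = 256 pairs of 2 x 4 structure matrices
#' (M1, M2), builds each network's transition matrix and keeps the
#' reachable ones. Exactly six distinct transition matrices survive; they
#' are returned in the canonical printed order of the six simplest forms,
#' each with its minimized per-node dynamics and its swap-coupled partner
#' (the form obtained by exchanging the two node labels).
#'
#' @return A list of six canonical forms; each element has fields `L`
#'   (a `transition_matrix`), `dynamics` (named list of minimized
#'   `boolean_expr` update rules), `network` (a `boolean_network`
#'   regenerating `L`) and `partner` (index in the list of the
#'   swap-coupled form).
#' @examples
#' forms <- enumerate_reachable_two_node()
#' forms[[1]]$L$successor  # 3 1 4 2
#' @export
enumerate_reachable_two_node <- function() {
  vars <- c("x1", "x2")
  seen <- list()
  for (m1 in 0:15) {
    t1 <- as.integer(intToBits(m1))[4:1]
    for (m2 in 0:15) {
      t2 <- as.integer(intToBits(m2))[4:1]
      # column j of L encodes the pair of next-node values at state j
      succ <- vapply(1:4, function(j) encode_state(c(t1[j], t2[j])),
                     integer(1))
      L <- new_transition_matrix(succ, 2L)
      if (!is_reachable_network(L)) next
      key <- paste(succ, collapse = ",")
      if (is.null(seen[[key]])) seen[[key]] <- L
    }
  }
  # canonical printed order of the six forms, keyed by successor tuple
  canon <- list(c(3L, 1L, 4L, 2L), c(2L, 4L, 1L, 3L), c(4L, 1L, 2L, 3L),
                c(4L, 3L, 1L, 2L), c(2L, 3L, 4L, 1L), c(3L, 4L, 2L, 1L))
  keys <- vapply(canon, paste, character(1), collapse = ",")
  found <- names(seen)
  if (!setequal(found, keys)) {
    # fall back to a stable lexicographic order if enumeration disagrees
    keys <- sort(found)
  }
  forms <- lapply(keys, function(k) {
    L <- seen[[k]]
    dyn <- simplest_dynamics_from_L(L, vars)
    net <- boolean_network(vapply(dyn, deparse_expression, character(1)))
    list(L = L, dynamics = dyn, network = net, partner = NA_integer_)
  })
  # swap-coupled partner: conjugate by the x1 <-> x2 state relabeling
  sigma <- vapply(1:4, function(j) encode_state(rev(decode_state(j, 2L))),
                  integer(1))
  succs <- lapply(forms, function(f) f$L$successor)
  for (i in seq_along(forms)) {
    s <- succs[[i]]
    conj <- integer(4)
    conj[sigma] <- sigma[s]
    forms[[i]]$partner <- which(vapply(succs, identical, logical(1), conj))
  }
  forms
}

#' Enumerate or count full-cycle transition matrices
#'
#' A full-cycle matrix is the transition matrix of a reachable n-node
#' network: a permutation of the 2^n states forming a single cycle. There
#' are (2^n - 1)! of them. Full enumeration is permitted for n <= 3 only;
#' for larger n the count is returned regardless of `count_only`.
#'
#' @param n number of nodes.
#' @param count_only if `TRUE` return only the count.
#' @return Either the count (a number) or a list of `transition_matrix`
#'   objects.
#' @examples
#' enumerate_full_cycle_matrices(2, count_only = TRUE)  # 6
#' @export
enumerate_full_cycle_matrices <- function(n, count_only = FALSE) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("`n` must be a positive integer")
  }
  d <- 2L^n
  if (n > 3L || count_only) {
    cnt <- factorial(d - 1)
    if (!count_only && n > 3L) {
      warning("full enumeration refused for n > 3; returning count")
    }
    return(cnt)
  }
  # single d-cycles <-> orderings of states 2..d after state 1
  perms <- all_permutations(seq(2L, length.out = d - 1L))
  lapply(perms, function(ord) {
    cyc <- c(1L, ord)
    succ <- integer(d)
    succ[cyc] <- c(cyc[-1L], cyc[1L])
    new_transition_matrix(succ, n)
  })
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Recover the simplest dynamics from a transition matrix
#'
#' Reads off each node's truth table from the transition matrix (bit i of
#' the decoded successor of every state) and minimizes it to sum-of-products
#' form. Rebuilding the transition matrix from the result is exact.
#'
#' @param L a `transition_matrix` (or anything accepted by
#'   [build_diagram()]).
#' @param node_names character vector of n node names.
#' @return Named list of minimized `boolean_expr` update rules.
#' @examples
#' dyn <- simplest_dynamics_from_L(transition_matrix_from_successor(c(3, 1, 4, 2)),
#'                                 c("x1", "x2"))
#' sapply(dyn, deparse_expression)
#' @export
simplest_dynamics_from_L <- function(L, node_names) {
  L <- as_transition_matrix(L)
  node_names <- as.character(node_names)
  n <- L$n
  if (length(node_names) != n) {
    stop("`node_names` must have one name per node")
  }
  next_bits <- t(vapply(L$successor, decode_state, integer(n), n = n))
  next_bits <- matrix(next_bits, ncol = n)
  dyn <- lapply(seq_len(n), function(i) {
    minimize_to_sop(next_bits[, i], node_names)
  })
  names(dyn) <- node_names
  dyn
}
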