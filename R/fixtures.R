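#' Random Boolean network
#'
#' Generates a closed n-node network by drawing a uniform random truth
#' table for each node and minimizing it to a sum-of-products update rule.
#' Uses R's RNG; set a seed for reproducibility.
#'
#' @param n number of nodes.
#' @param node_names optional names (default `x1..xn`).
#' @return A `boolean_network`.
#' @examples
#' set.seed(1)
#' random_network(3)
#' @export
random_network <- function(n, node_names = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (is.null(node_names)) node_names <- paste0("x", seq_len(n))
  updates <- vapply(seq_len(n), function(i) {
    tab <- sample(c(0L, 1L), 2L^n, replace = TRUE)
    deparse_expression(minimize_to_sop(tab, node_names))
  }, character(1))
  names(updates) <- node_names
  boolean_network(updates)
}

#' Random transition matrix
#'
#' Draws a random deterministic successor map on the 2^n integrated
#' states; with `permutation = TRUE` the map is a uniform random
#' permutation.
#'
#' @param n number of nodes.
#' @param permutation draw a permutation instead of an arbitrary map.
#' @return A `transition_matrix`.
#' @export
random_transition_matrix <- function(n, permutation = FALSE) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  d <- 2L^n
  succ <- if (permutation) sample.int(d) else sample.int(d, d, replace = TRUE)
  new_transition_matrix(succ, n)
}

#' Random full-cycle (reachable) transition matrix
#'
#' Draws a uniform random single-cycle permutation of the 2^n states — the
#' transition matrix of a random reachable network.
#'
#' @param n number of nodes.
#' @return A `transition_matrix` passing [is_reachable_network()].
#' @export
random_full_cycle_matrix <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  d <- 2L^n
  cyc <- c(1L, if (d > 2L) sample(seq(2L, d)) else if (d == 2L) 2L)
  succ <- integer(d)
  succ[cyc] <- c(cyc[-1L], cyc[1L])
  new_transition_matrix(succ, n)
}
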