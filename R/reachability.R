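#' Time transition diagram of a Boolean network
#'
#' The functional graph on the 2^n integrated states: state j has exactly
#' one outgoing edge, to `successor[j]`. The constructor also computes the
#' cycle decomposition (the attractors) and, for each state, the attractor
#' whose basin it belongs to.
#'
#' @param L a `transition_matrix` (or a `boolean_network`, converted
#'   internally).
#' @return An object of class `transition_diagram` with fields `n`,
#'   `successor`, `cycles` (list of integer vectors, each a directed cycle
#'   in traversal order) and `basin` (attractor number per state).
#' @examples
#' build_diagram(transition_matrix(p53_network()))
#' @export
build_diagram <- function(L) {
  L <- as_transition_matrix(L)
  succ <- L$successor
  nstate <- length(succ)
  # color: 0 unseen, -k on current path at depth k, >0 final attractor id
  basin <- integer(nstate)
  cycles <- list()
  for (start in seq_len(nstate)) {
    if (basin[start] != 0L) next
    path <- integer(0)
    v <- start
    while (basin[v] == 0L) {
      path <- c(path, v)
      basin[v] <- -length(path)
      v <- succ[v]
    }
    if (basin[v] < 0L) {
      # met our own path: new cycle from that point on
      at <- -basin[v]
      cyc <- path[at:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc
      cid <- length(cycles)
      basin[path] <- cid
    } else {
      basin[path] <- basin[v]
    }
  }
  structure(list(n = L$n, successor = succ, cycles = cycles, basin = basin),
            class = "transition_diagram")
}

as_transition_matrix <- function(L) {
  if (inherits(L, "transition_matrix")) return(L)
  if (inherits(L, "boolean_network")) return(transition_matrix(L))
  if (is.numeric(L) && is.null(dim(L))) {
    return(transition_matrix_from_successor(L))
  }
  if (is.matrix(L)) {
    lm <- as_logical_matrix(L)
    if (lm$rows != lm$cols) stop("transition matrix must be square")
    return(transition_matrix_from_successor(lm$col_index))
  }
  stop("cannot interpret `L` as a transition matrix")
}

#' @export
print.transition_diagram <- function(x, ...) {
  cat(sprintf("Time transition diagram: %d states, %d attractor%s\n",
              2L^x$n, length(x$cycles),
              if (length(x$cycles) == 1L) "" else "s"))
  for (i in seq_along(x$cycles)) {
    cyc <- x$cycles[[i]]
    cat(sprintf("  cycle %d (length %d): %s\n", i, length(cyc),
                paste(c(cyc, cyc[1]), collapse = " -> ")))
  }
  invisible(x)
}

#' Is a Boolean network reachable?
#'
#' A network is reachable iff every integrated state can be reached from
#' every initial state in finitely many steps — equivalently, iff the time
#' transition diagram is one directed cycle through all 2^n states (the
#' successor map is a single-orbit permutation).
#'
#' @inheritParams build_diagram
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_reachable_network(transition_matrix_from_successor(c(3, 1, 4, 2)))
#' @export
is_reachable_network <- function(L) {
  L <- as_transition_matrix(L)
  d <- build_diagram(L)
  length(d$cycles) == 1L && length(d$cycles[[1]]) == 2L^L$n
}

#' Classify reachable and non-reachable states
#'
#' A state is reachable if every initial state reaches it in at least one
#' step. For a deterministic map this is the unique attractor cycle's
#' states when the diagram has exactly one attractor; when two or more
#' attractors coexist no state is reachable from all initials, so the
#' reachable set is empty.
#'
#' @inheritParams build_diagram
#' @return An object of class `reachability_report` with fields
#'   `network_reachable`, `reachable_states`, `non_reachable_states`,
#'   `attractors` and `property_violations` (names of failed
#'   transition-matrix checks, see [check_matrix_properties()]).
#' @examples
#' classify_states(transition_matrix(p53_network()))
#' @export
classify_states <- function(L) {
  L <- as_transition_matrix(L)
  d <- build_diagram(L)
  all_states <- seq_len(2L^L$n)
  reach <- if (length(d$cycles) == 1L) sort(d$cycles[[1]]) else integer(0)
  checks <- check_matrix_properties(L)
  structure(list(
    n = L$n,
    network_reachable = is_reachable_network(L),
    reachable_states = reach,
    non_reachable_states = setdiff(all_states, reach),
    attractors = d$cycles,
    property_violations = names(checks)[!vapply(checks, isTRUE, logical(1))]),
    class = "reachability_report")
}

#' @export
print.reachability_report <- function(x, ...) {
  cat(sprintf("Reachability report (%d states)\n", 2L^x$n))
  cat(sprintf("  network reachable: %s\n",
              if (x$network_reachable) "yes" else "no"))
  cat(sprintf("  reachable states (%d): %s\n", length(x$reachable_states),
              if (length(x$reachable_states) == 0L) "none"
              else paste(x$reachable_states, collapse = " ")))
  cat(sprintf("  non-reachable states (%d): %s\n",
              length(x$non_reachable_states),
              if (length(x$non_reachable_states) == 0L) "none"
              else paste(x$non_reachable_states, collapse = " ")))
  cat(sprintf("  attractors: %d\n", length(x$attractors)))
  if (length(x$property_violations) > 0L) {
    cat("  failed matrix checks:",
        paste(x$property_violations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Structural checks on a transition matrix
#'
#' The three properties a reachable network's transition matrix satisfies:
#' \describe{
#'   \item{permutation}{exactly one 1 in each row and each column;}
#'   \item{zero_diagonal}{no state maps to itself;}
#'   \item{no_two_cycles}{no pair of states map to each other (checked for
#'     n >= 2 only; for n = 1 the unique reachable network is exactly the
#'     2-cycle, so the check does not apply and is reported `NA`).}
#' }
#'
#' @inheritParams build_diagram
#' @return Named list of `TRUE`/`FALSE` (or `NA` for an inapplicable
#'   check).
#' @export
check_matrix_properties <- function(L) {
  L <- as_transition_matrix(L)
  succ <- L$successor
  js <- seq_along(succ)
  perm <- !anyDuplicated(succ)
  zdiag <- !any(succ == js)
  two <- if (L$n >= 2L) !any(succ[succ] == js & succ != js) else NA
  list(permutation = perm, zero_diagonal = zdiag, no_two_cycles = two)
}

#' Export a transition diagram as Graphviz DOT
#'
#' One node per integrated state, one edge per state (to its successor).
#' Reachable states are highlighted; by default the highlight set comes
#' from [classify_states()].
#'
#' @param diagram a `transition_diagram` (or anything accepted by
#'   [build_diagram()]).
#' @param highlight optional integer vector of state indices to style as
#'   reachable.
#' @return A character scalar with the DOT source.
#' @examples
#' cat(export_dot(build_diagram(transition_matrix_from_successor(c(3, 1, 4, 2)))))
#' @export
export_dot <- function(diagram, highlight = NULL) {
  if (!inherits(diagram, "transition_diagram")) {
    diagram <- build_diagram(diagram)
  }
  nstate <- 2L^diagram$n
  if (is.null(highlight)) {
    highlight <- if (length(diagram$cycles) == 1L) diagram$cycles[[1]]
                 else integer(0)
  }
  lab <- function(j) sprintf("e%d_%d", nstate, j)
  nodes <- vapply(seq_len(nstate), function(j) {
    style <- if (j %in% highlight) {
      " [color=red, fontcolor=red, label=\"e_%d^%d\"]"
    } else {
      " [color=blue, fontcolor=blue, label=\"e_%d^%d\"]"
    }
    paste0("  ", lab(j), sprintf(style, nstate, j), ";")
  }, character(1))
  edges <- vapply(seq_len(nstate), function(j) {
    sprintf("  %s -> %s;", lab(j), lab(diagram$successor[j]))
  }, character(1))
  paste(c("digraph transition_diagram {", nodes, edges, "}", ""),
        collapse = "\n")
}
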