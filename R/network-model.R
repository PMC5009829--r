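#' Define a synchronous Boolean network
#'
#' A Boolean network is an ordered set of nodes, each updated synchronously
#' by a logical function of the current node values (and optionally of
#' declared control-input symbols). Update rules are given as expression
#' strings in the grammar of [parse_expression()].
#'
#' @param updates named character vector or named list of expression
#'   strings; names are the node names, in order. Each expression may
#'   reference any node or declared input.
#' @param inputs character vector of control-input symbol names (default
#'   none).
#' @return An object of class `boolean_network`.
#' @examples
#' net <- boolean_network(c(x1 = "!x2", x2 = "x1"))
#' transition_matrix(net)
#' @export
boolean_network <- function(updates, inputs = character()) {
  if (is.list(updates)) updates <- unlist(updates)
  nodes <- names(updates)
  if (is.null(nodes) || any(nodes == "") || anyDuplicated(nodes)) {
    stop("`updates` must have unique non-empty names (the node names)")
  }
  inputs <- as.character(inputs)
  if (any(inputs %in% nodes)) stop("input symbols must differ from node names")
  symbols <- c(nodes, inputs)
  exprs <- lapply(seq_along(updates), function(i) {
    parse_expression(updates[[i]], symbols)
  })
  names(exprs) <- nodes
  structure(list(nodes = nodes, updates = exprs, inputs = inputs),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d node%s", length(x$nodes),
              if (length(x$nodes) == 1L) "" else "s"))
  if (length(x$inputs) > 0L) {
    cat(sprintf(", input%s %s", if (length(x$inputs) == 1L) "" else "s",
                paste(x$inputs, collapse = ", ")))
  }
  cat("\n")
  for (nm in x$nodes) {
    cat(sprintf("  %s' = %s\n", nm, deparse_expression(x$updates[[nm]])))
  }
  invisible(x)
}

#' @export
summary.boolean_network <- function(object, ...) {
  if (length(object$inputs) > 0L) {
    print(object)
    cat("open network (has free inputs); bind inputs before analysis\n")
    return(invisible(object))
  }
  L <- transition_matrix(object)
  rep <- classify_states(L)
  print(object)
  cat(sprintf("reachable network: %s\n",
              if (rep$network_reachable) "yes" else "no"))
  cat(sprintf("attractors: %d; reachable states: %d of %d\n",
              length(rep$attractors), length(rep$reachable_states),
              2L^length(object$nodes)))
  invisible(object)
}

#' Close an open network by binding a control input
#'
#' Substitutes a feedback expression (over the nodes) for a declared input
#' symbol, yielding a closed network.
#'
#' @param net a `boolean_network` with at least one input.
#' @param input name of the input symbol to bind.
#' @param expression expression string over the node names.
#' @return A closed `boolean_network`.
#' @export
bind_input <- function(net, input, expression) {
  stopifnot(inherits(net, "boolean_network"))
  if (!input %in% net$inputs) {
    stop(sprintf("'%s' is not a declared input of the network", input))
  }
  sub <- parse_expression(expression, net$nodes)
  subst <- function(e) {
    e <- unclass(e)
    switch(e$op,
      const = e,
      var = if (e$name == input) unclass(sub) else e,
      not = list(op = "not", arg = subst(e$arg)),
      list(op = e$op, lhs = subst(e$lhs), rhs = subst(e$rhs)))
  }
  updates <- vapply(net$nodes, function(nm) {
    deparse_expression(structure(subst(net$updates[[nm]]),
                                 class = "boolean_expr"))
  }, character(1))
  boolean_network(updates, inputs = setdiff(net$inputs, input))
}

# --- transition matrices --------------------------------------------------

#' Transition matrix of a closed Boolean network
#'
#' The unique 2^n x 2^n logical matrix L with x(k+1) = L stp x(k): column j
#' is the basis vector of the successor of integrated state j. Two
#' constructions are available and agree exactly: direct state enumeration
#' (evaluate every update at every state; the normative definition) and the
#' algebraic STP product
#' \deqn{L = M_1 \ltimes \prod_{i=2}^{n} [(I_{2^n} \otimes M_i) \ltimes \Phi_n]}
#' over the per-node structure matrices.
#'
#' @param net a closed `boolean_network` (no free inputs).
#' @param method `"direct"` (default) or `"stp"`.
#' @return An object of class `transition_matrix` holding the successor
#'   index list; `as.matrix()` densifies it.
#' @examples
#' net <- boolean_network(c(x1 = "!x2", x2 = "x1"))
#' transition_matrix(net)$successor  # 3 1 4 2
#' @export
transition_matrix <- function(net, method = c("direct", "stp")) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(net$inputs) > 0L) {
    stop("network has free inputs; bind them first (see bind_input())")
  }
  method <- match.arg(method)
  if (method == "direct") transition_matrix_direct(net)
  else transition_matrix_stp(net)
}

transition_matrix_direct <- function(net) {
  n <- length(net$nodes)
  succ <- vapply(seq_len(2L^n), function(j) {
    bits <- decode_state(j, n)
    names(bits) <- net$nodes
    nxt <- vapply(net$updates, evaluate_expression, integer(1),
                  assignment = bits)
    encode_state(nxt)
  }, integer(1))
  new_transition_matrix(succ, n)
}

transition_matrix_stp <- function(net) {
  n <- length(net$nodes)
  Ms <- lapply(net$updates, function(e) {
    as.matrix(structure_matrix(e, net$nodes))
  })
  phi <- as.matrix(power_reducing_matrix(n))
  L <- Ms[[1]]
  if (n > 1L) {
    id <- diag(2L^n)
    for (i in 2:n) {
      L <- stp(L, stp(kronecker(id, Ms[[i]]), phi))
    }
  }
  if (!all(dim(L) == c(2L^n, 2L^n))) {
    stop("internal consistency failure: STP product has wrong dimensions")
  }
  lm <- as_logical_matrix(L)
  new_transition_matrix(lm$col_index, n)
}

new_transition_matrix <- function(successor, n) {
  structure(list(n = as.integer(n), successor = as.integer(successor)),
            class = "transition_matrix")
}

#' Build a transition matrix from a successor index list
#'
#' @param successor integer vector of length 2^n; entry j is the state
#'   index that integrated state j maps to (column j of L is the basis
#'   vector at that row).
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix_from_successor <- function(successor) {
  successor <- as.integer(successor)
  n <- round(log2(length(successor)))
  if (2L^n != length(successor)) {
    stop("`successor` length must be a power of 2")
  }
  if (anyNA(successor) || any(successor < 1L | successor > length(successor))) {
    stop("`successor` entries must lie in 1:length(successor)")
  }
  new_transition_matrix(successor, n)
}

#' @export
as.matrix.transition_matrix <- function(x, ...) {
  as.matrix(logical_matrix(x$successor, rows = 2L^x$n))
}

#' @export
print.transition_matrix <- function(x, ...) {
  d <- 2L^x$n
  cat(sprintf("Transition matrix L (%d x %d), %d node%s\n", d, d, x$n,
              if (x$n == 1L) "" else "s"))
  cat("L = (", paste(sprintf("e_%d^%d", d, x$successor), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.transition_matrix <- function(x) c(2L^x$n, 2L^x$n)

# --- network file format --------------------------------------------------

#' Read a Boolean network from a text file
#'
#' Format: one `name = expression` line per node (in node order), optional
#' `input <symbol>` declarations, `#` comments and blank lines ignored.
#'
#' @param path file path.
#' @return A `boolean_network`.
#' @examples
#' path <- system.file("extdata", "p53.bn", package = "bnreach")
#' read_network(path)
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  inputs <- character()
  nms <- character()
  exprs <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^input\\s+", ln)) {
      inputs <- c(inputs, trimws(sub("^input\\s+", "", ln)))
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      nms <- c(nms, trimws(substr(ln, 1L, eq - 1L)))
      exprs <- c(exprs, trimws(substr(ln, eq + 1L, nchar(ln))))
    } else {
      stop(sprintf("%s: cannot parse line %d: '%s'", path, i, ln))
    }
  }
  if (length(nms) == 0L) stop(sprintf("%s: no node definitions found", path))
  names(exprs) <- nms
  boolean_network(exprs, inputs = inputs)
}

#' Write a Boolean network to a text file
#'
#' @param net a `boolean_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  lines <- c(
    sprintf("input %s", net$inputs),
    vapply(net$nodes, function(nm) {
      sprintf("%s = %s", nm, deparse_expression(net$updates[[nm]]))
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' The bundled p53 major-switch network
#'
#' The four-gene negative-feedback switch of the p53 pathway with nodes
#' ATM, p53, Wip1, Mdm2 (in that order):
#' ATM' = !Wip1; p53' = ATM & !Mdm2; Wip1' = p53; Mdm2' = !ATM & (p53 | Wip1).
#'
#' @return A `boolean_network` with 4 nodes.
#' @examples
#' summary(p53_network())
#' @export
p53_network <- function() {
  read_network(system.file("extdata", "p53.bn", package = "bnreach"))
}
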