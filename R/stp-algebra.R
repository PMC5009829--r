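#' Semi-tensor product of two matrices
#'
#' The semi-tensor product (STP) generalizes the ordinary matrix product to
#' factors whose inner dimensions need not match:
#' \deqn{A \ltimes B = (A \otimes I_{\alpha/n})(B \otimes I_{\alpha/p}),}
#' where \eqn{A} is \eqn{m \times n}, \eqn{B} is \eqn{p \times q}, and
#' \eqn{\alpha = \mathrm{lcm}(n, p)}. When \eqn{n = p} both Kronecker factors
#' are identities and the STP reduces to the ordinary product. The STP is
#' associative, so chained products may be evaluated left to right.
#'
#' @param A,B numeric matrices (vectors are treated as single-column
#'   matrices).
#' @return The numeric matrix \eqn{A \ltimes B}.
#' @examples
#' x1 <- boolean_vector(1)  # (1,0)^T
#' x0 <- boolean_vector(0)  # (0,1)^T
#' stp(x1, x0)              # e_4^2: joint state (1,0)
#' @seealso [power_reducing_matrix()], [encode_state()]
#' @export
stp <- function(A, B) {
  A <- as_matrix2(A)
  B <- as_matrix2(B)
  n <- ncol(A)
  p <- nrow(B)
  a <- lcm2(n, p)
  left <- if (a == n) A else kronecker(A, diag(a / n))
  right <- if (a == p) B else kronecker(B, diag(a / p))
  left %*% right
}

# coerce vectors to column matrices without copying matrices
as_matrix2 <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

lcm2 <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a / g(a, b) * b
}

#' Semi-tensor product of several matrices
#'
#' Evaluates `stp(...)` over a list of factors left to right (valid by
#' associativity).
#'
#' @param ... matrices, or a single list of matrices.
#' @return The chained semi-tensor product.
#' @export
stp_chain <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.matrix(args[[1]])) {
    args <- args[[1]]
  }
  stopifnot(length(args) >= 1L)
  Reduce(stp, args)
}

#' Power-reducing matrix
#'
#' The fixed \eqn{2^{2n} \times 2^n} logical matrix \eqn{\Phi_n} that
#' collapses a repeated state factor in an STP product:
#' \eqn{x \ltimes x = \Phi_n \ltimes x} for every integrated-state basis
#' vector \eqn{x = e_{2^n}^j}. Column \eqn{j} has its single 1 at row
#' \eqn{(j-1)2^n + j}.
#'
#' @param n number of network nodes (positive integer).
#' @return A [logical_matrix] of size \eqn{2^{2n} \times 2^n}.
#' @examples
#' as.matrix(power_reducing_matrix(1))
#' @export
power_reducing_matrix <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  d <- 2L^as.integer(n)
  j <- seq_len(d)
  logical_matrix(col_index = (j - 1L) * d + j, rows = d * d)
}

#' Boolean value as a canonical basis vector
#'
#' Encodes a Boolean scalar in vector form: 1 (true) as
#' \eqn{e_2^1 = (1,0)^T}, 0 (false) as \eqn{e_2^2 = (0,1)^T}.
#'
#' @param value 0 or 1 (logicals are accepted).
#' @return A 2 x 1 numeric matrix.
#' @export
boolean_vector <- function(value) {
  value <- as.integer(value)
  if (length(value) != 1L || is.na(value) || !value %in% c(0L, 1L)) {
    stop("`value` must be a single 0 or 1")
  }
  matrix(c(value, 1L - value), ncol = 1L)
}

#' Encode node values as an integrated state
#'
#' Maps an ordered tuple of n Boolean node values to the index j of the
#' basis vector \eqn{e_{2^n}^j} representing the joint (integrated) state.
#' The convention puts the all-ones state first (j = 1) and the all-zeros
#' state last (j = 2^n):
#' \deqn{j = 2^n - \sum_{i=1}^{n} b_i\, 2^{n-i}.}
#' This equals the chained STP of the per-node Boolean vectors.
#'
#' @param bits ordered 0/1 vector of node values (node 1 first).
#' @return The state index j in `1:2^length(bits)`.
#' @examples
#' encode_state(c(0, 0, 1))      # 7
#' encode_state(c(1, 1, 1, 1))   # 1
#' @seealso [decode_state()]
#' @export
encode_state <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 1L || anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must be a non-empty 0/1 vector")
  }
  n <- length(bits)
  as.integer(2L^n - sum(bits * 2L^(n - seq_len(n))))
}

#' Decode an integrated state back to node values
#'
#' Inverse of [encode_state()]: recovers the ordered 0/1 node values from a
#' state index.
#'
#' @param index state index in `1:2^n`.
#' @param n number of nodes.
#' @return Integer 0/1 vector of length n (node 1 first).
#' @examples
#' decode_state(7, 3)   # c(0, 0, 1)
#' @export
decode_state <- function(index, n) {
  index <- as.integer(index)
  n <- as.integer(n)
  if (length(index) != 1L || is.na(index) || index < 1L || index > 2L^n) {
    stop("`index` must lie in 1:2^n")
  }
  v <- 2L^n - index
  as.integer(intToBits(v))[n:1]
}

#' Logical matrix in column-index form
#'
#' A logical matrix is a 0/1 matrix in which every column is a canonical
#' basis vector; it is stored compactly as the row index of the single 1 in
#' each column. Structure matrices of Boolean functions, transition
#' matrices, the power-reducing matrix and the dummy operator are all
#' logical matrices.
#'
#' @param col_index integer vector; entry j is the row holding the 1 in
#'   column j.
#' @param rows number of rows.
#' @return An object of class `logical_matrix`.
#' @examples
#' M <- logical_matrix(c(2, 1), rows = 2)  # negation
#' as.matrix(M)
#' @export
logical_matrix <- function(col_index, rows) {
  col_index <- as.integer(col_index)
  rows <- as.integer(rows)
  if (length(rows) != 1L || is.na(rows) || rows < 1L) {
    stop("`rows` must be a positive integer")
  }
  if (length(col_index) < 1L || anyNA(col_index) ||
      any(col_index < 1L | col_index > rows)) {
    stop("`col_index` entries must lie in 1:rows")
  }
  structure(list(rows = rows, cols = length(col_index),
                 col_index = col_index),
            class = "logical_matrix")
}

#' @export
as.matrix.logical_matrix <- function(x, ...) {
  m <- matrix(0L, nrow = x$rows, ncol = x$cols)
  m[cbind(x$col_index, seq_len(x$cols))] <- 1L
  m
}

#' Coerce a dense 0/1 matrix to column-index form
#'
#' @param m a 0/1 matrix with exactly one 1 per column.
#' @return A [logical_matrix].
#' @export
as_logical_matrix <- function(m) {
  if (inherits(m, "logical_matrix")) return(m)
  m <- as_matrix2(m)
  if (!all(m %in% c(0, 1)) || !all(colSums(m) == 1)) {
    stop("`m` is not a logical matrix (one 1 per column, rest 0)")
  }
  logical_matrix(apply(m, 2L, which.max), rows = nrow(m))
}

#' @export
print.logical_matrix <- function(x, ...) {
  cat(sprintf("<logical matrix %d x %d>\n", x$rows, x$cols))
  cat("column indices:", paste(x$col_index, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.logical_matrix <- function(x) c(x$rows, x$cols)
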