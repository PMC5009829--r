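#' Parse a Boolean expression
#'
#' Parses a text expression over declared variables into an abstract syntax
#' tree. The grammar accepts the ASCII operator aliases
#' `!` (not), `&` (and), `|` (or), `^` (xor), `->` (implies),
#' `<-` (converse implication), `<->` (biconditional), `nand`, `nor`,
#' constants `0`/`1`/`false`/`true`, and parentheses. Unicode synonyms
#' (\"¬ ∧ ∨ ⊕ → ← ↔ ⇔ ↑ ↓ ⊤ ⊥\") are accepted. Precedence, high to low:
#' `!`, `&`, `|`, then the xor/implication/nand/nor family (left
#' associative); parentheses override.
#'
#' @param text expression string.
#' @param variables ordered character vector of declared variable names.
#' @return An object of class `boolean_expr`.
#' @examples
#' e <- parse_expression("(!x1 & !x2) | x1", c("x1", "x2"))
#' truth_table(e, c("x1", "x2"))
#' @export
parse_expression <- function(text, variables) {
  stopifnot(is.character(text), length(text) == 1L)
  variables <- as.character(variables)
  toks <- tokenize_expr(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- parse_low(st, variables, text)
  if (st$pos <= length(st$toks)) {
    tk <- st$toks[[st$pos]]
    stop(sprintf("parse error at position %d: unexpected '%s'",
                 tk$at, tk$text))
  }
  structure(expr, class = "boolean_expr")
}

# --- tokenizer ------------------------------------------------------------

# unicode operator synonyms normalized before scanning
normalize_expr_text <- function(text) {
  subs <- c("¬" = "!", "∧" = "&", "∨" = "|",
            "⊕" = "^", "→" = "->", "←" = "<-",
            "↔" = "<->", "⇔" = "<->", "↑" = " nand ",
            "↓" = " nor ", "⊤" = "1", "⊥" = "0")
  for (k in names(subs)) text <- gsub(k, subs[[k]], text, fixed = TRUE)
  text
}

tokenize_expr <- function(text) {
  s <- normalize_expr_text(text)
  toks <- list()
  i <- 1L
  nc <- nchar(s)
  while (i <= nc) {
    rest <- substr(s, i, nc)
    if (grepl("^\\s", rest)) {
      i <- i + 1L
      next
    }
    m <- regmatches(rest, regexpr(
      "^(<->|->|<-|[!&|^()]|[A-Za-z_][A-Za-z0-9_.]*|[01])", rest))
    if (length(m) == 0L) {
      stop(sprintf("parse error at position %d: unexpected character '%s'",
                   i, substr(s, i, i)))
    }
    toks[[length(toks) + 1L]] <- list(text = m, at = i)
    i <- i + nchar(m)
  }
  toks
}

peek_tok <- function(st) {
  if (st$pos > length(st$toks)) NULL else st$toks[[st$pos]]
}

take_tok <- function(st) {
  tk <- peek_tok(st)
  st$pos <- st$pos + 1L
  tk
}

# --- recursive-descent parser ---------------------------------------------

# lowest level: xor / implications / biconditional / nand / nor
parse_low <- function(st, vars, src) {
  lhs <- parse_or(st, vars, src)
  repeat {
    tk <- peek_tok(st)
    op <- if (is.null(tk)) NULL else switch(tk$text,
      "^" = "xor", "->" = "imply", "<-" = "implied",
      "<->" = "iff", "nand" = "nand", "nor" = "nor", NULL)
    if (is.null(op)) return(lhs)
    take_tok(st)
    rhs <- parse_or(st, vars, src)
    lhs <- list(op = op, lhs = lhs, rhs = rhs)
  }
}

parse_or <- function(st, vars, src) {
  lhs <- parse_and(st, vars, src)
  while (!is.null(tk <- peek_tok(st)) && tk$text == "|") {
    take_tok(st)
    lhs <- list(op = "or", lhs = lhs, rhs = parse_and(st, vars, src))
  }
  lhs
}

parse_and <- function(st, vars, src) {
  lhs <- parse_unary(st, vars, src)
  while (!is.null(tk <- peek_tok(st)) && tk$text == "&") {
    take_tok(st)
    lhs <- list(op = "and", lhs = lhs, rhs = parse_unary(st, vars, src))
  }
  lhs
}

parse_unary <- function(st, vars, src) {
  tk <- peek_tok(st)
  if (is.null(tk)) stop("parse error: unexpected end of expression")
  if (tk$text == "!") {
    take_tok(st)
    return(list(op = "not", arg = parse_unary(st, vars, src)))
  }
  if (tk$text == "(") {
    take_tok(st)
    e <- parse_low(st, vars, src)
    cl <- take_tok(st)
    if (is.null(cl) || cl$text != ")") {
      stop(sprintf("parse error at position %d: expected ')'", tk$at))
    }
    return(e)
  }
  take_tok(st)
  if (tk$text %in% c("0", "false")) return(list(op = "const", value = 0L))
  if (tk$text %in% c("1", "true")) return(list(op = "const", value = 1L))
  if (tk$text %in% vars) return(list(op = "var", name = tk$text))
  stop(sprintf("parse error at position %d: undeclared symbol '%s'",
               tk$at, tk$text))
}

# --- evaluation -----------------------------------------------------------

#' Evaluate a Boolean expression under a total assignment
#'
#' @param expr a `boolean_expr` (or raw AST node).
#' @param assignment named 0/1 vector covering every variable in `expr`.
#' @return 0 or 1.
#' @export
evaluate_expression <- function(expr, assignment) {
  e <- unclass(expr)
  switch(e$op,
    const = e$value,
    var = {
      v <- assignment[[e$name]]
      if (is.null(v) || is.na(v)) stop(sprintf("unbound symbol '%s'", e$name))
      as.integer(v)
    },
    not = 1L - evaluate_expression(e$arg, assignment),
    {
      a <- evaluate_expression(e$lhs, assignment)
      b <- evaluate_expression(e$rhs, assignment)
      switch(e$op,
        and = a & b,
        or = a | b,
        xor = (a + b) %% 2L,
        imply = (1L - a) | b,
        implied = a | (1L - b),
        iff = as.integer(a == b),
        nand = 1L - (a & b),
        nor = 1L - (a | b),
        stop(sprintf("unknown operator '%s'", e$op))) |> as.integer()
    })
}

#' Variables referenced by an expression
#' @param expr a `boolean_expr`.
#' @return Character vector of symbol names (may be empty).
#' @export
expression_variables <- function(expr) {
  e <- unclass(expr)
  switch(e$op,
    const = character(),
    var = e$name,
    not = expression_variables(e$arg),
    unique(c(expression_variables(e$lhs), expression_variables(e$rhs))))
}

# --- serialization --------------------------------------------------------

#' Serialize a Boolean expression to canonical ASCII
#'
#' Emits the expression with the ASCII operator aliases and only the
#' parentheses required by precedence; `parse_expression()` of the result
#' is semantically identical to the input.
#'
#' @param expr a `boolean_expr`.
#' @return A single string.
#' @export
deparse_expression <- function(expr) {
  dep <- function(e, parent_prec) {
    prec <- switch(e$op, const = , var = 5L, not = 4L, and = 3L, or = 2L, 1L)
    s <- switch(e$op,
      const = as.character(e$value),
      var = e$name,
      not = paste0("!", dep(e$arg, 4L)),
      {
        sym <- switch(e$op, and = "&", or = "|", xor = "^", imply = "->",
                      implied = "<-", iff = "<->", nand = "nand", nor = "nor")
        paste(dep(e$lhs, prec), sym, dep(e$rhs, prec + 1L))
      })
    if (prec < parent_prec) paste0("(", s, ")") else s
  }
  dep(unclass(expr), 0L)
}

#' @export
print.boolean_expr <- function(x, ...) {
  cat(deparse_expression(x), "\n")
  invisible(x)
}

#' @export
format.boolean_expr <- function(x, ...) deparse_expression(x)

# --- truth tables and structure matrices ----------------------------------

#' Truth table of a Boolean expression
#'
#' Entry j (1-based) is the expression evaluated at the assignment
#' `decode_state(j, k)`, i.e. rows follow the integrated-state order with
#' the all-ones assignment first — the column order of the structure
#' matrices, not the usual all-zeros-first convention.
#'
#' @param expr a `boolean_expr`.
#' @param variables ordered character vector of length k; must cover the
#'   expression's symbols.
#' @return Integer 0/1 vector of length `2^k`.
#' @export
truth_table <- function(expr, variables) {
  variables <- as.character(variables)
  k <- length(variables)
  miss <- setdiff(expression_variables(expr), variables)
  if (length(miss) > 0L) {
    stop(sprintf("expression uses undeclared symbols: %s",
                 paste(miss, collapse = ", ")))
  }
  vapply(seq_len(2L^k), function(j) {
    bits <- decode_state(j, k)
    names(bits) <- variables
    evaluate_expression(expr, bits)
  }, integer(1))
}

#' Structure matrix of a Boolean function
#'
#' The 2 x 2^k logical matrix M with
#' \eqn{f(x_1, \ldots, x_k) = M \ltimes x_1 \ltimes \cdots \ltimes x_k}:
#' column j is the Boolean vector of the truth-table entry at integrated
#' state j.
#'
#' @inheritParams truth_table
#' @return A [logical_matrix] with 2 rows and `2^k` columns.
#' @examples
#' e <- parse_expression("x1 & x2", c("x1", "x2"))
#' as.matrix(structure_matrix(e, c("x1", "x2")))
#' @export
structure_matrix <- function(expr, variables) {
  tt <- truth_table(expr, variables)
  logical_matrix(col_index = 2L - tt, rows = 2L)
}

# --- exact two-level minimization -----------------------------------------

#' Minimal sum-of-products expression for a truth table
#'
#' Exact two-level minimization: Quine-McCluskey prime implicants followed
#' by a Petrick-style exhaustive cover search. Among minimal covers, ties
#' are broken by fewer total literals, then by the lexicographically
#' smallest serialized form, so the result is deterministic. Constant
#' tables return the constants `1` / `0`.
#'
#' @param table 0/1 vector of length `2^k`, ordered as [truth_table()]
#'   (all-ones assignment first).
#' @param variables ordered character vector of length k.
#' @return A `boolean_expr` in sum-of-products form whose truth table
#'   equals `table`.
#' @examples
#' vars <- c("x1", "x2")
#' minimize_to_sop(c(0, 0, 1, 1), vars)  # !x1
#' @export
minimize_to_sop <- function(table, variables) {
  variables <- as.character(variables)
  k <- length(variables)
  table <- as.integer(table)
  if (length(table) != 2L^k || !all(table %in% c(0L, 1L))) {
    stop("`table` must be a 0/1 vector of length 2^length(variables)")
  }
  ones <- which(table == 1L)
  if (length(ones) == 0L) {
    return(structure(list(op = "const", value = 0L), class = "boolean_expr"))
  }
  if (length(ones) == 2L^k) {
    return(structure(list(op = "const", value = 1L), class = "boolean_expr"))
  }
  # implicants are character masks over bit values: "0", "1", "-"
  minterms <- vapply(ones, function(j) {
    paste(decode_state(j, k), collapse = "")
  }, character(1))
  primes <- qm_prime_implicants(minterms, k)
  cover <- qm_min_cover(primes, minterms, k)
  terms <- lapply(cover, implicant_to_term, variables = variables)
  # canonical ordering of product terms
  terms <- terms[order(vapply(terms, deparse_expression, character(1)))]
  expr <- Reduce(function(a, b) list(op = "or", lhs = a, rhs = b), terms)
  structure(expr, class = "boolean_expr")
}

# Quine-McCluskey prime implicant generation over mask strings
qm_prime_implicants <- function(minterms, k) {
  current <- unique(minterms)
  primes <- character()
  while (length(current) > 0L) {
    combined <- character()
    used <- logical(length(current))
    mat <- do.call(rbind, strsplit(current, ""))
    if (length(current) > 1L) {
      for (i in seq_len(length(current) - 1L)) {
        for (j in seq(i + 1L, length(current))) {
          diff <- which(mat[i, ] != mat[j, ])
          if (length(diff) == 1L && mat[i, diff] != "-" &&
              mat[j, diff] != "-") {
            merged <- mat[i, ]
            merged[diff] <- "-"
            combined <- c(combined, paste(merged, collapse = ""))
            used[i] <- used[j] <- TRUE
          }
        }
      }
    }
    primes <- c(primes, current[!used])
    current <- unique(combined)
  }
  unique(primes)
}

implicant_covers <- function(mask, minterm) {
  m <- strsplit(mask, "")[[1]]
  t <- strsplit(minterm, "")[[1]]
  all(m == "-" | m == t)
}

# Exhaustive minimum-cover search (k <= 6 keeps this small): fewest terms,
# then fewest literals, then lexicographically smallest serialized set.
qm_min_cover <- function(primes, minterms, k) {
  covers <- vapply(primes, function(p) {
    vapply(minterms, function(m) implicant_covers(p, m), logical(1))
  }, logical(length(minterms)))
  covers <- matrix(covers, nrow = length(minterms))
  nlit <- vapply(primes, function(p) sum(strsplit(p, "")[[1]] != "-"),
                 integer(1))
  np <- length(primes)
  best <- NULL
  best_key <- NULL
  for (size in seq_len(np)) {
    combos <- utils::combn(np, size, simplify = FALSE)
    for (sel in combos) {
      cov <- if (length(sel) == 1L) covers[, sel] else rowSums(covers[, sel, drop = FALSE]) > 0
      if (all(cov)) {
        key <- list(sum(nlit[sel]),
                    paste(sort(primes[sel]), collapse = "|"))
        if (is.null(best) || key[[1]] < best_key[[1]] ||
            (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]])) {
          best <- primes[sel]
          best_key <- key
        }
      }
    }
    if (!is.null(best)) break
  }
  best
}

implicant_to_term <- function(mask, variables) {
  bits <- strsplit(mask, "")[[1]]
  lits <- list()
  for (i in seq_along(bits)) {
    if (bits[i] == "1") {
      lits[[length(lits) + 1L]] <- list(op = "var", name = variables[i])
    } else if (bits[i] == "0") {
      lits[[length(lits) + 1L]] <- list(op = "not",
                                        arg = list(op = "var",
                                                   name = variables[i]))
    }
  }
  if (length(lits) == 0L) return(list(op = "const", value = 1L))
  Reduce(function(a, b) list(op = "and", lhs = a, rhs = b), lits)
}
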