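#' Simulate a Boolean network trajectory
#'
#' Iterates the successor map from an initial state. The returned
#' trajectory records the visited integrated states, the per-node 0/1 time
#' series, and — once the run is long enough to revisit a state — the
#' attractor cycle and the transient prefix before it.
#'
#' @param x a `boolean_network`, `transition_matrix`, or successor vector.
#' @param initial the initial state: either a 0/1 vector of node values or
#'   a single integrated-state index in `1:2^n`.
#' @param steps number of steps to iterate (default `2 * 2^n + 1`, which
#'   always suffices to enter and identify the attractor).
#' @param node_names optional node names for the per-node series (taken
#'   from the network when `x` is one).
#' @return An object of class `bn_trajectory` with fields `states`
#'   (indices, length `steps + 1`), `transient` (states before the
#'   attractor), `period` (attractor cycle length, `NA` if not yet
#'   detected), `cycle` (the attractor states in traversal order) and
#'   `series` (a `(steps+1) x n` 0/1 matrix of node values over time).
#' @examples
#' traj <- simulate_network(p53_network(), initial = 8)
#' traj$period  # 6
#' @export
simulate_network <- function(x, initial, steps = NULL, node_names = NULL) {
  if (inherits(x, "boolean_network") && is.null(node_names)) {
    node_names <- x$nodes
  }
  L <- as_transition_matrix(x)
  n <- L$n
  if (is.null(node_names)) node_names <- paste0("x", seq_len(n))
  if (length(initial) > 1L) {
    initial <- encode_state(initial)
  } else {
    initial <- as.integer(initial)
    if (is.na(initial) || initial < 1L || initial > 2L^n) {
      stop(sprintf("`initial` must be a state index in 1:%d or a 0/1 tuple",
                   2L^n))
    }
  }
  if (is.null(steps)) steps <- 2L * 2L^n + 1L
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 0L) stop("`steps` must be >= 0")
  states <- integer(steps + 1L)
  states[1L] <- initial
  for (t in seq_len(steps)) states[t + 1L] <- L$successor[states[t]]
  # detect the first revisited state: everything from its first visit on
  # is periodic, everything before is the transient
  dup <- which(duplicated(states))[1L]
  if (!is.na(dup)) {
    first <- match(states[dup], states)
    period <- dup - first
    transient <- if (first > 1L) states[seq_len(first - 1L)] else integer(0)
    cycle <- states[first:(dup - 1L)]
  } else {
    period <- NA_integer_
    transient <- integer(0)
    cycle <- integer(0)
  }
  series <- t(vapply(states, decode_state, integer(n), n = n))
  series <- matrix(series, ncol = n, dimnames = list(NULL, node_names))
  structure(list(n = n, node_names = node_names, states = states,
                 transient = transient, period = period, cycle = cycle,
                 series = series),
            class = "bn_trajectory")
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%d nodes, %d steps)\n", x$n,
              length(x$states) - 1L))
  show <- utils::head(x$states, 20L)
  cat("  states:", paste(show, collapse = " -> "),
      if (length(x$states) > 20L) "..." else "", "\n")
  if (!is.na(x$period)) {
    cat(sprintf("  transient length %d, period %d (%s-phase)\n",
                length(x$transient), x$period,
                if (length(x$transient) == 0L) "one" else "two"))
  }
  invisible(x)
}

#' Split a trajectory into transient and periodic phases
#'
#' Decomposes a trajectory into the transient prefix (the states visited
#' before the attractor is entered) and the periodic attractor cycle. A
#' trajectory starting on the attractor is a one-phase (purely periodic)
#' pulse: its transient is empty. Any other start gives a two-phase pulse:
#' transient then steady-state cycle.
#'
#' @param traj a `bn_trajectory` long enough to revisit a state
#'   (`2^n + 1` steps always suffice).
#' @return A list with `transient` (integer vector, possibly empty),
#'   `cycle` (integer vector), `period` and `phases` (1 or 2).
#' @examples
#' decompose_phases(simulate_network(p53_network(), initial = 1))
#' @export
decompose_phases <- function(traj) {
  stopifnot(inherits(traj, "bn_trajectory"))
  if (is.na(traj$period)) {
    stop("trajectory too short to detect a revisit; use more steps")
  }
  list(transient = traj$transient, cycle = traj$cycle,
       period = traj$period,
       phases = if (length(traj$transient) == 0L) 1L else 2L)
}

#' Per-node pulse table of a trajectory
#'
#' One row per time step, one 0/1 column per node (high expression = 1);
#' suitable for CSV export and for plotting square-wave expression pulses.
#'
#' @param traj a `bn_trajectory`.
#' @param node_names optional column names overriding the trajectory's.
#' @return A `data.frame` with columns `time`, `state` (integrated-state
#'   index) and one 0/1 column per node.
#' @examples
#' head(pulse_table(simulate_network(p53_network(), initial = 8, steps = 6)))
#' @export
pulse_table <- function(traj, node_names = NULL) {
  stopifnot(inherits(traj, "bn_trajectory"))
  if (is.null(node_names)) node_names <- traj$node_names
  df <- data.frame(time = seq_along(traj$states) - 1L,
                   state = traj$states)
  ser <- traj$series
  colnames(ser) <- node_names
  cbind(df, as.data.frame(ser))
}

#' @export
as.data.frame.bn_trajectory <- function(x, ...) pulse_table(x)

#' Plot expression pulses of a trajectory
#'
#' Draws each node's 0/1 time series as a stacked square wave.
#'
#' @param x a `bn_trajectory`.
#' @param ... further arguments passed to `plot()`.
#' @return `x`, invisibly.
#' @export
plot.bn_trajectory <- function(x, ...) {
  n <- x$n
  tt <- seq_along(x$states) - 1L
  graphics::plot(range(tt), c(0, 1.5 * n), type = "n", xlab = "step",
                 ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = 1.5 * (seq_len(n) - 1L) + 0.5,
                 labels = x$node_names, las = 1)
  for (i in seq_len(n)) {
    off <- 1.5 * (i - 1L)
    graphics::lines(tt, off + x$series[, i], type = "s", col = i)
  }
  invisible(x)
}
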