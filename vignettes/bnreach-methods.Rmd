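---
title: "Methods: Boolean network reachability and feedback control with the semi-tensor product"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean network reachability and feedback control with the semi-tensor product}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnreach)
```

## The model

A synchronous Boolean network has n nodes with values in {0, 1} — in
gene-network applications, high versus low expression — each updated at
every discrete step by a fixed logical function of the current node values.
The model's assumptions are strong and worth stating: updates are
deterministic, simultaneous, and time-invariant; expression is binarized;
there is no noise. Within those assumptions the dynamics are a function on
a finite set, so every trajectory must enter a cycle, and every global
question (which states recur, which are transient, which can be forced) is
decidable by finite computation. This package makes those computations
convenient and exact for networks up to roughly 20 nodes (the dense 2^n
representation is the limit, and most curated regulatory switches are far
smaller).

## Algebraic state space

Boolean values are carried as canonical basis vectors, 1 as (1,0)^T and 0
as (0,1)^T, and the joint ("integrated") state of n nodes as the basis
vector of dimension 2^n equal to the iterated semi-tensor product (STP) of
the per-node vectors. The STP of an m x n matrix A and a p x q matrix B is

$$A \ltimes B = (A \otimes I_{\alpha/n})(B \otimes I_{\alpha/p}),
  \qquad \alpha = \mathrm{lcm}(n, p),$$

an associative product that reduces to the ordinary one when n = p. Two
classical facts make it useful here: every logical function of k variables
has a 2 x 2^k *structure matrix* M with
$f(x_1,\dots,x_k) = M \ltimes x_1 \ltimes \cdots \ltimes x_k$, and every
closed network has a unique 2^n x 2^n *transition matrix* L with
$x(t+1) = L \ltimes x(t)$.

Two conventions fix all indexing, and both are load-bearing for every
number the package prints:

* **State order.** The all-ones state is index 1 and the all-zeros state is
  index 2^n ($j = 2^n - \sum_i b_i 2^{n-i}$). Truth tables and structure
  matrices use the same order, *not* the common all-zeros-first convention.
* **1-based indices** throughout, matching the superscript in $e_{2^n}^j$.

`transition_matrix()` offers two constructions. Direct enumeration —
evaluate every update at every state — is the normative definition.
The algebraic product

$$L = M_1 \ltimes \prod_{i=2}^{n}\left[(I_{2^n} \otimes M_i) \ltimes
  \Phi_n\right]$$

is evaluated left to right (legitimate by associativity) with the
power-reducing matrix $\Phi_n$ (column j has its 1 at row $(j-1)2^n + j$),
which collapses the repeated state factor via
$x \ltimes x = \Phi_n \ltimes x$. The printed 16 x 4 form of $\Phi_2$ is
kept as a conformance fixture in the tests, while the $x \ltimes x$
contract is the normative definition for general n. Because the dimension
bookkeeping of the product formula is easy to get wrong, the package treats
agreement of the two constructions as an internal invariant: the test suite
checks it on exhaustive and random networks up to n = 6, and the
command-line `matrix` command cross-checks on every run.

`logical_matrix` objects store only the row index of each column's single
1; dense 0/1 matrices are materialized just inside `stp()` and at I/O
boundaries. Transition matrices are therefore successor index lists, which
makes cycle analysis linear in 2^n.

## Expressions and exact minimization

Update rules are parsed from text over the sixteen binary logical operators
with ASCII aliases (`! & | ^ -> <- <-> nand nor`, constants `0`/`1`) and
Unicode synonyms; precedence is `!` > `&` > `|` > the xor/implication
family, with parentheses overriding. A concrete grammar is the package's
own choice — the underlying theory uses operator symbols only.

"Simplest form" of a Boolean function is not a mathematically fixed notion;
this package takes it to mean exact two-level minimization: Quine–McCluskey
prime implicants followed by an exhaustive Petrick-style minimum-cover
search, ties broken by fewer product terms, then fewer literals, then the
lexicographically smallest serialization. The result is deterministic and
reproduces the textbook minimal forms of all the small worked examples
(e.g. `!x2` from its truth table, and the three-term feedback law below).
Exact covering is exponential in the worst case; it is intended for the
k ≤ 4 functions that arise in these analyses (`random_network()` uses it
too, and is likewise meant for small n).

## Reachability from the time transition diagram

The *time transition diagram* is the functional graph on the 2^n integrated
states with the single outgoing edge j → successor(j). A state is
*reachable* if every initial state reaches it in at least one step; the
"at least one" matters, because it lets the states on an attractor cycle
count as reachable from themselves around the loop while excluding
self-loops. A network is reachable iff its diagram is one directed cycle
through all 2^n states — equivalently L is a single-orbit permutation. The
transition matrix of a reachable network then has one 1 per row and column,
a zero diagonal, and (for n ≥ 2) no two-cycles; the unique reachable 1-node
network *is* the 2-cycle, so the last check is reported `NA` at n = 1.

Two consequences the package states explicitly because they are easy to
miss: with exactly one attractor, the reachable set is exactly that cycle's
states (everything else is transient); with two or more attractors, *no*
state is reachable from all initials, so the reachable set is empty.
`classify_states()` implements exactly this case split, and the exhaustive
n = 2 test (all 256 successor maps) confirms the equivalence of the
graphical test, the matrix property checks, and the classification.

## The six two-node forms and block-doubling control

For n = 2 the per-node structure matrices have 2^4 admissible values each;
scanning all 256 pairs and keeping the reachable networks leaves exactly
six distinct transition matrices. They are reported in a fixed canonical
order (keyed by successor tuple, matching the order in which the six forms
are conventionally printed) with their minimized dynamics; swapping the two
node labels pairs them into three couples, which the enumeration verifies
by conjugating each L with the swap permutation.

Lifting a reachable n-node network to n + 1 nodes replaces each nonzero
cell (i, j) of L — each "1-block" — by a 2 x 2 block: *identity* sends the
doubled states (2j−1, 2j) to (2i−1, 2i), *skew* sends them to (2i, 2i−1).
Collapsing the blocks recovers the base matrix, and the lift of a reachable
base is reachable **iff the number of skew blocks is odd**: traversing the
base cycle composes the blocks, and the two lifted sheets are exchanged iff
the number of swaps is odd. The qualitative statement of this parity rule
can be read two ways (odd identities or odd skews); the skew reading is the
one consistent with the sheet-exchange argument, and the package verifies
it exhaustively — all 16 assignments over the two-node base, and sampled
three-node bases — against `is_reachable_network()` on the constructed
lift.

`synthesize_feedback_control()` turns this into a constructive design for
lower-triangle networks (first n nodes do not depend on the appended node,
which carries the input): lift the base transition matrix under an
odd-parity assignment, read the appended node's truth table off the lifted
matrix, and minimize it. The default assignment puts the single skew block
on the base 1-block with the largest column index — a deterministic choice
that reproduces the standard worked example on the base
`x1' = !x2, x2' = x1`, giving

```{r}
law <- synthesize_feedback_control(
  boolean_network(c(x1 = "!x2", x2 = "x1")), "x3")
law$u
```

and a closed loop that is a single 8-cycle. Any explicit assignment may be
supplied; even parity is refused with an error naming the rule. Equivalence
with a published form of u is always checked at truth-table level, since
sum-of-products representations are not unique.

## Simulation and pulse phases

`simulate_network()` iterates the successor map; the default horizon
2·2^n + 1 guarantees that some state repeats, so the attractor is always
identified. The trajectory splits into the transient prefix — states
visited *before the first state that belongs to the attractor* — and the
periodic cycle. A start on the attractor yields a one-phase (purely
periodic) pulse; any other start yields a two-phase pulse. Note the
boundary case: a transient that ends by landing on a cycle state counts
that state as part of the cycle, not the transient (for the bundled p53
switch started from state 1, the transient is (1, 14) and the cycle is
entered at state 15). Time steps are abstract; no physical time scale is
modeled.

For the bundled p53 major switch (ATM, p53, Wip1, Mdm2) the unique
attractor has period 6 and every one of the 16 initial states enters it
within 10 steps; `pulse_table()` exports the per-node square waves:

```{r}
head(pulse_table(simulate_network(p53_network(), initial = 8, steps = 6)))
```

## Random fixtures and what the tests show

Property tests draw random networks and random transition matrices under
fixed seeds: uniform random truth tables per node (minimized for n ≤ 4,
raw minterm expansions in the test helpers for n = 5, 6), uniform random
successor maps, permutations and single-cycle permutations. These fixtures
cover the discrete objects the theory quantifies over — for the exhaustive
claims (n = 2 maps, 16 operators, 16 block assignments) the tests enumerate
the whole space, so "passing" is a proof for those sizes rather than a
sample. What the fixtures do *not* emulate is anything about real
regulatory data: no asynchrony, no stochasticity, no parameter noise, no
binarization error. Passing tests certify the algebra and the
combinatorics, not the biological fidelity of any particular Boolean
abstraction.

Problem sizes used in the suite — exhaustive enumeration at n ≤ 3 (5040
full-cycle matrices), random cross-checks at n ≤ 6, and all worked examples
at n ≤ 4 — keep the whole suite around ten seconds while exercising every
code path at sizes where independent oracles (brute-force Kronecker
expansion, plain truth-table iteration) are feasible.

## Known limitations

* Dense 2^n state spaces: no sparse or symbolic (BDD) backend, so n beyond
  ~20 is out of reach by design.
* Synchronous deterministic updates only; no probabilistic or asynchronous
  semantics.
* Exact minimization is exponential in the worst case and intended for
  small k.
* Reachability here is the autonomous notion (modify the initial state,
  then let the network run free); controllability under a time-varying
  exogenous input sequence is a different theory and out of scope, as is
  output-feedback design.
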