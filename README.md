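# bnreach

Reachability analysis and state-feedback control of synchronous Boolean
networks via the semi-tensor product (STP) of matrices.

Boolean networks model gene-regulatory and signalling circuits as n nodes
with values in {0, 1}, updated synchronously by logical functions of the
current state. `bnreach` is for systems and computational biologists who
want to answer, for such a circuit: *which joint expression states can the
network ever reach, from any starting condition?* and *if a desired state is
unreachable, what feedback input makes it reachable?*

## The algebra at the core

Each Boolean value is a canonical basis vector (1 ↦ (1,0)ᵀ, 0 ↦ (0,1)ᵀ) and
the joint state of n nodes is the basis vector eⱼ of dimension 2ⁿ (all-ones
state first: j = 1; all-zeros: j = 2ⁿ). With the semi-tensor product

    A ⋉ B = (A ⊗ I_{α/n}) (B ⊗ I_{α/p}),   α = lcm(cols(A), rows(B)),

every logical function of k variables becomes a 2 × 2ᵏ *structure matrix* M
with f(x₁, …, x_k) = M ⋉ x₁ ⋉ ⋯ ⋉ x_k, and the whole network becomes one
2ⁿ × 2ⁿ *transition matrix* L with x(k+1) = L ⋉ x(k). `bnreach` builds L two
ways — direct state enumeration and the algebraic product
L = M₁ ⋉ ∏ᵢ [(I_{2ⁿ} ⊗ Mᵢ) ⋉ Φₙ] with the power-reducing matrix Φₙ — and
cross-checks them.

Reachability is then graph theory on the *time transition diagram* (the
functional graph of L): the network is reachable iff the diagram is a single
directed cycle through all 2ⁿ states, and the reachable states of a
non-reachable network are exactly its unique attractor cycle (empty if
several attractors coexist). On top of this the package:

* enumerates all 256 two-node structure-matrix pairs and recovers the six
  simplest reachable two-node networks with their minimized dynamics;
* lifts a reachable n-node network to n + 1 nodes by block doubling
  (identity/skew 2 × 2 blocks; the lift is reachable iff the skew count is
  odd) and extracts the state-feedback law u for the appended node by exact
  Quine–McCluskey minimization;
* simulates trajectories, decomposing them into transient ("two-phase") and
  periodic ("one-phase") pulses.

## Worked example: the p53 major switch

The bundled four-gene switch (ATM, p53, Wip1, Mdm2):

```r
library(bnreach)
p53 <- p53_network()
p53
#> Boolean network: 4 nodes
#>   ATM' = !Wip1
#>   p53' = ATM & !Mdm2
#>   Wip1' = p53
#>   Mdm2' = !ATM & (p53 | Wip1)

L <- transition_matrix(p53)
L
#> Transition matrix L (16 x 16), 4 nodes
#> L = (e_16^14, e_16^10, e_16^6, e_16^2, e_16^16, e_16^12, e_16^8, e_16^4,
#>      e_16^13, e_16^13, e_16^5, e_16^5, e_16^15, e_16^15, e_16^8, e_16^8)

classify_states(L)
#> Reachability report (16 states)
#>   network reachable: no
#>   reachable states (6): 2 4 8 10 13 15
#>   non-reachable states (10): 1 3 5 6 7 9 11 12 14 16
#>   attractors: 1
#>   failed matrix checks: permutation
```

Column j of L is the one-step successor of integrated state j, so state 1
(all four genes high) moves to state 14 (Wip1 high only), and state 8 (ATM
high only) moves to state 4. The six reachable states form the unique
attractor 8 → 4 → 2 → 10 → 13 → 15 → 8: a period-6 expression pulse. Any
other start shows a two-phase pulse — a short transient, then the cycle:

```r
simulate_network(p53, initial = 1, steps = 12)
#> Trajectory (4 nodes, 12 steps)
#>   states: 1 -> 14 -> 15 -> 8 -> 4 -> 2 -> 10 -> 13 -> 15 -> 8 -> 4 -> 2 -> 10
#>   transient length 2, period 6 (two-phase)
```

Control synthesis on the simplest reachable two-node base appends a third
node and returns the feedback law closing a single 8-cycle:

```r
base <- boolean_network(c(x1 = "!x2", x2 = "x1"))
synthesize_feedback_control(base, "x3")
#> State-feedback control law
#>   u = !x1 & !x2 & !x3 | x1 & x3 | x2 & x3
#>   closed loop (3 nodes) reachable: yes
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/bnreach.R reach inst/extdata/p53.bn --dot
Rscript inst/cli/bnreach.R control inst/extdata/three_node_control.bn
```

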