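# retromra

Modular Response Analysis (MRA) for signaling networks whose modules are
bridged by enzyme–substrate complexes.

## The problem

MRA reconstructs the direct connections between network modules from
steady-state responses to perturbations.  Writing `x_i` for the output
(communicating species) of module `i`, the global response coefficients

    R_ij = d ln x_i / d p_j   (at steady state)

are measured for perturbation parameters `p_j`, and the connection (local
response) coefficients `r_ij` — the direct influence of module `j` on
module `i` with all other modules held fixed — are recovered row by row
from the MRA equations

    sum_k r_ik R_kj = 0,   r_ii = -1,

using, for each row `i`, `N − 1` perturbations that do not directly affect
module `i` (the *module insulation condition*).

Kinases bind their substrates.  When an appreciable share of an active
kinase from module `i` is sequestered in a complex with a substrate from
module `j`, that complex carries mass across the module boundary:
perturbing the substrate's abundance drags the kinase along
(*retroactivity*).  Insulation breaks, the inferred circuitry starts to
depend on which abundances were perturbed, and spurious
sequestration-induced connections appear alongside the real regulatory
ones.

`retromra` implements the weighted-output extension of MRA that repairs
this.  The module output is redefined as a weighted sum of the free active
enzyme and the inter-modular complex, e.g.

    x_1(a) = [ppMEK] + a · [ppMEK··ERK],

and the connection coefficients are recomputed for a range of weights `a`
from a *single* table of perturbation responses.  Coefficients that change
sign along the scan are sequestration-induced; the weight `a_opt` at which
they vanish (for the MEK/ERK motif, analytically `a_opt = k1/(k1 + k2)`)
restores the insulation condition, makes the inferred matrix invariant to
the choice of permissible perturbations, and cleanly separates regulatory
from retroactive connections.

The package provides:

* mass-action reaction networks with non-competitive regulatory
  multipliers, exact (rational) moiety-conservation analysis, and a tight
  two-phase steady-state solver (stiff integration + Newton polishing);
* a model library: the two-module MEK/ERK benchmark and three-tier
  kinase cascades with optional positive/negative feedback, plus a
  seeded parameter sampler with controllable sequestration strength;
* perturbation simulation (default 10% central differences), reweighable
  global response matrices, lognormal measurement noise;
* the MRA solver with per-row perturbation assignment, condition-number
  diagnostics and an invariance (insulation) check;
* weight scans, root finding for nullifying weights, connection
  classification, and sum-of-squares minimization for topologies where
  exact nullification is impossible;
* a small CLI (`simulate` / `infer` / `scan`) over plain text formats.

## Worked example

```r
library(retromra)

p    <- build_mek_erk()                      # frozen strong-sequestration defaults
tab  <- run_perturbations(p$network, p$params, c("MEK_tot", "ERK_tot"))
part <- preset_partition(p, "asymmetric")    # x1 = [ppMEK] + a*[ppMEK..ERK]
asg  <- assign_perturbations(part, c("MEK_tot", "ERK_tot"),
                             preset_permissible(p), preset_direct_targets(p))

# the historic choice a = 1 (measure total phosphoforms):
solve_connection_matrix(global_responses(tab, part, c(a = 1)), asg)
#>           MEK       ERK
#> MEK -1.000000  0.359072
#> ERK  0.417302 -1.000000
```

At `a = 1` the inferred feedback `r_12 = 0.359` says ERK *activates* MEK —
a false positive.  At `a = 0` (free phosphoforms) the same table gives
`r_12 = -0.318`: now ERK appears to *inhibit* MEK.  Scanning the weight
and nullifying the sign-changing entry resolves the contradiction:

```r
opt <- find_a_opt(tab, part, asg, targets = list(c(1, 2)))
opt$weights
#>         a
#> 0.2914827
p$params[["k1"]] / (p$params[["k1"]] + p$params[["k2"]])
#> [1] 0.2914827                      # the analytic a_opt = k1/(k1+k2)

classify_connections(scan_weights(tab, part, asg))
#>     MEK          ERK
#> MEK NA           "sequestration"
#> ERK "regulatory" NA
```

The MEK→ERK edge is regulatory (its coefficient never changes sign); the
apparent ERK→MEK feedback is pure sequestration and vanishes at `a_opt`,
where the connection matrix also becomes invariant to the choice of
perturbed parameters (`invariance_check()`).

The same machinery handles three-tier cascades
(`build_cascade3("none" | "3to1" | "3to2", u, k_fb)`): jointly nullifying
`r_12` and `r_23` also clears the skip-level `r_13` when no feedback
exists, leaves `r_13` standing (with the sign of `u1 − 1`) when tier 3
regulates tier 1, and discriminates a strong tier-3→tier-2 regulatory
feedback (`u2 = 50.5`, `r_23` keeps its sign) from a weak one
(`u2 = 1.75`, sequestration dominates and `r_23` flips).

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mra.R", package = "retromra"))') \
  scan --model cascade3_none --perturb X1_tot --perturb X2_tot --perturb X3_tot \
  --out runs/cascade
```

writes the tidy weight scan, the classification and the nullifying
weights; `simulate` and `infer` cover the earlier stages.  Exit codes: 0
ok, 2 configuration error, 3 numerical failure.

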