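# azeopatch

Azeotropy-by-design for multicomponent patchy-particle mixtures.

Multicomponent self-assembly designs (e.g. DNA-origami colloids that build
a target crystal from several particle species) face a thermodynamic
hazard: phase separation can change the local composition away from the
stoichiometry of the target structure and stall the assembly.  At an
**azeotropic point** this hazard disappears — the coexisting phases keep
the composition of the parent mixture, so the mixture condenses and
crystallises like an effective one-component fluid.

`azeopatch` provides the complete tool-chain for engineering azeotropy
into patchy-particle designs and validating it, from the interaction
matrix to the phase diagram to direct simulation:

* **Design rules** on the patch-color interaction matrix ϒ (symmetric,
  0/1).  If every patch has exactly one bonding partner (*bond
  exclusivity*), the law of mass action
  X<sub>α</sub><sup>(i)</sup> = [1 + ρ Σ<sub>j</sub> x<sup>(j)</sup>
  Σ<sub>γ∈Γ(j)</sub> ϒ<sub>αγ</sub> Δ X<sub>γ</sub><sup>(j)</sup>]<sup>−1</sup>
  admits a uniform solution X at the equimolar composition — an azeotrope.
  The *bond multiplicity* rule moves the azeotrope to x = (1/(n+1),
  n/(n+1)); the *fully connected* rule makes every composition azeotropic.
  Checkers, a rule-satisfying matrix generator, and the reduced scalar
  equation (ρΔw·X² + X − 1 = 0 with rule weight w) are included.
* **Wertheim first-order perturbation theory** for the mixture:
  βf = βf<sub>ideal</sub> + βf<sub>CS</sub> + Σ<sub>i</sub> x<sup>(i)</sup>
  Σ<sub>α</sub>(ln X<sub>α</sub><sup>(i)</sup> − X<sub>α</sub><sup>(i)</sup>/2 + 1/2),
  with Δ = V<sub>b</sub>(e<sup>βϵ</sup> − 1)⟨g<sub>HS</sub>⟩; Gibbs
  free-energy minimisation, common-tangent coexistence at fixed (T, P),
  and an azeotrope locator.
* **Isochoric thermodynamics**: binodal tracing by integrating
  dρ′/dP = H′<sup>−1</sup>v, dρ″/dP = H″<sup>−1</sup>v with Newton
  projection back onto the equal-P, equal-μ manifold, and critical points
  from det H<sub>Ψ</sub> = 0.
* A compiled **Kern–Frenkel Monte Carlo engine**: NVT and Gibbs-ensemble
  sampling with rototranslation and aggregation-volume-bias (AVB) moves,
  bond/cluster analysis, and a dihedral-based cubic- vs hexagonal-diamond
  detector — used to cross-validate the theory on the N2c8s2 binary
  mixture that assembles cubic diamond through an equimolar azeotrope.

## Worked example

```r
library(azeopatch)
mix <- build_n2c8s2()
print(mix)
#> patchy mixture: 2 species, 4 patches each, 8 colors
#> composition: 0.5, 0.5
#> Kern-Frenkel parameters: epsilon = 1, delta = 0.2, cos(theta_max) = 0.98, sigma = 1

rule <- check_bond_exclusivity(mix)
print(rule)
#> design rule 'exclusivity': satisfied
#> predicted azeotrope: x = ( 0.5, 0.5 )

st <- thermo_state(temperature = 0.08, density = 0.3, composition = c(0.5, 0.5))
X <- solve_mass_balance(mix, st)
X[1, 1]                       # all 8 patch probabilities are equal
#> 0.2143079
solve_azeotropic_x(rule, st$packing_fraction, bond_integral(mix$kf, 0.08, 0.3))
#> 0.2143079                   # reduced scalar equation agrees exactly

print(helmholtz_free_energy(mix, st))
#> beta*f: ideal -2.897120 + hard-sphere 0.780134 + bonding -4.589981 = -6.706968

az <- azeotrope_point(mix, 0.07)
sprintf("azeotrope at T = 0.07: x = %.5f, P = %.3e", az$x_az, az$P_az)
#> "azeotrope at T = 0.07: x = 0.49995, P = 7.632e-06"
```

The last call bisects the coexistence lens in pressure: dew and bubble
curves of the binary mixture meet tangentially at the lens *minimum*
(a negative azeotrope) at the equimolar composition — exactly where the
exclusivity rule predicted it from the interaction matrix alone, with no
phase-diagram input.  `trace_binodal()` reproduces the same curve from the
isochoric side, and `run_gibbs()` reproduces the separation into two
equimolar branches in direct simulation.

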