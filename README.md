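# beedyn — honey bee colony population dynamics

`beedyn` implements a two-compartment model of the adult worker population
of a honey bee (*Apis mellifera*) colony, for researchers studying colony
failure, division of labour, and the demographic consequences of forager
mortality. Adult workers are either **hive bees** (H), which rear brood and
essentially do not die, or **foragers** (F), which die at per-capita rate
*m* per day. The model couples the two castes through brood eclosion and
socially inhibited recruitment:

    dH/dt = E(H, F) − H · R(H, F)
    dF/dt = H · R(H, F) − m · F

with the saturating eclosion function and the recruitment function

    E(H, F) = L · N / (w + N),        N = H + F
    R(H, F) = α − σ · F / N

Here *L* is the queen's laying rate (eggs/day), *w* the colony size at
which brood rearing reaches half its maximum, *α* the uninhibited
recruitment rate to foraging (1/day), and *σ* the strength of social
inhibition: foragers suppress the hive-bee-to-forager transition in
proportion to the forager fraction of the workforce (the ethyl-oleate
feedback). Negative *R* means foragers revert to hive tasks, which with the
default *α/σ* = 1/3 happens only when more than a third of the workforce
forages.

The model has a closed-form steady state. Writing *J* for the equilibrium
forager-to-hive ratio — the positive root of
*m J² + (m + σ − α) J − α = 0* — the equilibrium hive-bee population is
*H₀ = L/(mJ) − w/(1+J)*, which is positive exactly when
*m J/(1+J) < L/w*. Above a **critical forager death rate m\*** (0.355/day
at the default parameters, i.e. a mean foraging life of only 2.8 days) no
positive equilibrium exists and the colony inevitably collapses. The
package also provides an optional precocious-foraging mortality feedback in
which *m* is replaced by the Hill response *m_l R²/(σ̄² + R²)*, and
demographic predictions: the average age at onset of foraging
(AAOF = 1/(mJ) at equilibrium) and worker lifespan (AAOF + 1/m).

## Worked example

```r
library(beedyn)

steady_state(bee_params(m = 0.24))
#> Colony steady state (m = 0.24 /day)
#>   viable: H0 = 6470.04, F0 = 1987.76, N0 = 8457.81 bees (J = 0.30723)
#>   eigenvalues: -0.01438+0i -0.83013+0i /day

critical_death_rate(bee_params())
#> [1] 0.3551967
```

A colony losing foragers at rate 0.24/day settles at about 8 458 adult
bees, roughly one forager for every 3.3 hive bees; both eigenvalues are
negative, so the state is stable, and the slow eigenvalue (−0.014/day)
shows the population adjusts over weeks while the caste ratio (fast
eigenvalue, −0.83/day) rebalances within days. Raising the death rate past
0.355/day removes the equilibrium entirely:

```r
simulate_colony(bee_params(m = 0.40), c(H = 9000, F = 0), 2500,
                output_step = 25) |> tail(1)
#>        t            H            F           N            E          R m_eff
#> 101 2500 0.0001722445 4.337655e-05 0.000215621 1.597193e-05 0.09912228   0.4
```

Demographic predictions over a 40-day observation window, compared with
mark–recapture field observations of four reference colonies:

```r
table1_report()
#>   colony flightspan deathrate AAOF_obs AAOF_model lifespan_obs lifespan_model
#> 1      1        7.5     0.133     18.6   19.37437         22.8       26.89317
#> 2      2        6.5     0.154     18.4   17.72506         22.3       24.21857
#> 3      3        6.7     0.149     23.8   17.55977         26.6       24.27118
#> 4      4        8.8     0.114     22.2   20.44162         26.4       29.21355
```

Each colony's forager death rate is the reciprocal of its observed
flightspan; the model's AAOF tracks the observations to within a few days,
and lifespan is AAOF plus flightspan by construction.

## Command line

A thin front-end is installed at `exec/beedyn`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","beedyn",package="beedyn"))')" \
    bifurcation --m-min 0.05 --m-max 0.6 --steps 200 --out scan.csv
```

Subcommands: `simulate --config FILE --out FILE`, `equilibrium --m RATE`,
`bifurcation`, `demography --m RATE | --fixture N`, `table1`. Rates are in
1/day, populations in bees, times in days. Output CSVs serialise numbers
with 10 significant digits, so identical configurations give byte-identical
files.

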