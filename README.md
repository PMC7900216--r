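# mtMisalign

Misalignment-length signatures of mitochondrial DNA deletion breakpoints.

Mitochondrial DNA deletions are widely thought to arise when single-stranded
segments of the L- and H-strands hybridize at non-allelic positions
("misalignment") during double-strand-break repair or replication.  Different
repair pathways use characteristically different homology lengths (NHEJ
0-5 nt, micro-homology-mediated end joining up to ~25 nt, recombination-like
pathways >= 50 nt), so the *length* of the misalignment associated with a
catalog of deletions is a mechanistic signature.  `mtMisalign` estimates that
signature for breakpoint catalogs on circular mitochondrial genomes.

## The model

For a deletion with breakpoints (p5, p3), a 201-nt L-strand window centered
on p5 and a 201-nt H-strand window centered on p3 define a 201 x 201 window
of analysis.  For each position pair and each duplex length
l in {0, 5, 10, 15, 20, 25, 50, 75, 100} nt, the *misalignment propensity*
is the sum over the l x l duplexes overlapping the pair of the hybridization
partition function

    Z = sum over duplex configurations exp(-dG / RT),

computed under nearest-neighbor thermodynamics (unified Watson-Crick dG37
parameters plus published internal single-mismatch contexts; helices of
stacked pairs separated by Jacobson-Stockmayer loops/bulges; duplex
initiation and terminal A.T penalties).  Propensities are summed into
10 x 10-nt bins and normalized within the window; the entry of interest is
the relative propensity p_l of the bin containing the breakpoint, with
p_0 = 1/400 for the hybridization-independent component.  For a catalog of n
deletions the mixture weights theta on the length grid maximize

    L(theta) = sum_i log( sum_l theta_l * p_{i,l} ),   theta on the simplex,

via EM; theta_l is the fraction of deletions attributable to l-nt
misalignments, reported per length and grouped as short (0-5), medium
(10-25) and long (>= 50) with parametric-bootstrap standard deviations.

## Worked example

Simulate a breakpoint catalog with known mixture structure on a synthetic
16-kb circular genome and re-estimate the weights:

```r
library(mtMisalign)
params <- load_nn_parameters()           # unified DNA/DNA dG37 set
spec   <- simulation_spec(seed = 11)     # n = 2000, theta* = (0.2 @ l=0,
                                         #  0.5 @ l=5, 0.3 @ l=20)
genome <- synthetic_genome(spec)
eng    <- propensity_engine(genome, params, spec$grid)
cat    <- simulate_breakpoints(genome, spec, params, engine = eng)
fit    <- fit_mixture(component_matrix(cat, spec$grid, params, engine = eng))
print(fit)
```

```
MixtureFit: n = 2000 , loglik = -11104.77
     0      5     10     15     20     25     50     75    100
0.1708 0.5374 0.0000 0.0124 0.2795 0.0000 0.0000 0.0000 0.0000
grouped: short 0.708 medium 0.292 long 0
```

The fitted weights recover the simulated truth (0.2 at l = 0, 0.5 at l = 5,
0.3 at l = 20) to within a few percent per length: 71% of the simulated
deletions are attributed to short (0-5 nt) misalignments and 29% to the
medium class, and the long components are correctly absent.  A
single-breakpoint profile - here for the catalog's most frequent pair -
gives the relative breakpoint-bin propensity per grid length:

```r
prof <- breakpoint_profile(genome, p5 = 3091, p3 = 9121, params = params)
round(prof, 5)
```

```
      0       5      10      15      20      25      50      75     100
0.00250 0.00533 0.01687 0.01387 0.01169 0.00823 0.00038 0.00006 0.00003
```

The l = 0 entry is exactly the uniform 1/400 = 0.0025; this breakpoint's
bin is about seven times more propense than uniform for 10-nt misalignments
and essentially silent beyond 50 nt, so short-to-medium misalignment best
explains it.  `flanking_repeat_length()` reports the classical direct-repeat
annotation for comparison.

Real catalogs are loaded with `read_genome()` (FASTA; the reference is the
L-strand) and `load_breakpoints()` (TSV/CSV with dataset, species, p5, p3
columns; positions are 1-based and validated against the genome).  A thin
command-line wrapper with subcommands `fit`, `profile`, `simulate` and
`validate` is installed at `exec/mtmisalign`.

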