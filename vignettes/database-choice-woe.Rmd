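---
title: "Database choice and Fst-adjusted weight of evidence for STR profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Database choice and Fst-adjusted weight of evidence for STR profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strwoe)
```

## The problem

When a court weighs the evidence that a queried individual Q contributed
to a crime-scene DNA profile (CSP), the likelihood-ratio framework
compares a prosecution hypothesis including Q with a defence hypothesis
in which an unknown, unrelated individual X replaces Q.  Evaluating the
defence likelihood requires allele frequencies for X — but X's ancestry
is generally unknown, and the number of populations one could consider is
unlimited.  Common practice is to compute the weight of evidence (WoE,
log10 of the likelihood ratio, in bans) under every available population
database and report the smallest.  For mixtures with several unknown
contributors this becomes combinatorially expensive.

`strwoe` implements a single-calculation policy: use only the database
that best matches the ancestry of Q, for every unknown contributor,
together with a deliberately generous coancestry adjustment
(Fst = 0.03).  The package also implements the alternative
database-assignment policies and a simulation study measuring how often
the single-database policy is *conservative* — i.e. yields a WoE no
larger than the alternative — under controlled conditions.

## The probability model

### Sampling formula

Allele probabilities for unknowns assigned the database of Q use the
Balding–Nichols sampling formula.  Writing $p_a$ for the reference
fraction of allele $a$ and $\theta$ for the coancestry coefficient
(Fst), the probability that the next sampled allele is of type $a$,
given $m$ copies of $a$ among $n$ already observed, is

$$\Pr(a \mid m, n) = \frac{m\theta + (1-\theta)p_a}{1 + (n-1)\theta}.$$

Genotype probabilities are products of two sequential draws (the second
conditioning on the first), doubled for heterozygotes.  At $\theta = 0$
this is exactly Hardy–Weinberg; for any $(m, n)$ the probabilities sum
to 1 over the allele set.

### Conditioning policy

* An unknown assigned the database of Q is conditioned on Q's two
  alleles at each locus, with $\theta = 0.03$ (the policy default).
* An unknown assigned any other database uses $\theta = 0$ and,
  equivalently, empty conditioning — the formula is then the plain
  product of reference fractions.
* The alleles of a profiled second contributor K never enter the
  conditioning: the adjustment raises the probability of the alleles of
  Q only.
* When both unknowns X and U are assigned the database of Q, the default
  is the full sequential recursion: U conditions on Q's alleles *and* on
  the genotype drawn for X (`condition_on_unknowns = TRUE`).  The
  switch exists because one could defensibly treat the two unknowns as
  coming from distinct subpopulations; the default follows standard
  sequential-sampling practice, and the alternative is available for
  sensitivity analysis.

### Size-bias count adjustment

In every calculation, one observation is added to the database count for
each allele *copy* of Q (a homozygote adds two counts to its single
allele; the per-locus total always rises by two).  We read "one per
allele" as one per copy rather than one per distinct allele because it
treats heterozygotes and homozygotes symmetrically in added
observations; the distinct-allele reading would add less weight to
homozygous loci.  A side effect is that the alleles of Q always have
nonzero frequency under every analysis database.

Other CSP or conditioning alleles can still carry zero observations in a
cross-database analysis; such alleles are floored to count 1 (with a
warning unless `quiet = TRUE`).  Without a floor the defence likelihood
could be exactly zero and the WoE infinite, which no forensic reporting
framework accepts.

### Hypothesis pairs

Three hypothesis pairs are supported, all with no dropout or dropin (the
CSP is exactly the union of the contributors' alleles):

* `lr_single()` — Hp: Q vs Hd: X.  The LR is the reciprocal match
  probability.
* `lr_known()` — Hp: Q+K vs Hd: X+K.  Hp likelihood is 1 (the CSP is
  deterministic given both genotypes); Hd sums over genotypes of X
  within the CSP alleles that cover the alleles K does not explain.
* `lr_unknown()` — Hp: Q+U vs Hd: X+U.  Hp sums over genotypes of U
  completing Q to the CSP; Hd sums over ordered genotype pairs (X, U)
  whose union equals the CSP allele set.

Per-locus LRs are computed in linear space (magnitudes are moderate at
single loci), logged, and summed across loci in log space (linkage
equilibrium).  Genotype enumeration is restricted to CSP alleles, since
any allele outside the CSP would imply dropout.  Two-contributor CSPs
have at most 4 alleles per locus, so the enumeration is over at most 10
unordered genotypes and 100 ordered pairs; three or more contributors
are out of scope.

## When is the adjustment conservative?

For the single-contributor case the policy is conservative exactly when
$\theta$ raises the match probability.  This is *not* a theorem for all
frequencies: for a heterozygote whose two alleles are both common
(frequency sum above roughly 0.8), the $(1+\theta)(1+2\theta)$
denominators outweigh the numerator boost and the adjusted match
probability decreases.  For STR loci, where individual allele
frequencies rarely approach 0.4, the adjustment is effectively always
favourable — but the existence of the reversal is the analytical reason
the simulation study finds *almost*-always rather than always
conservative behaviour.  The test suite asserts monotonicity in the
rare-allele regime and asserts the common-allele reversal explicitly.

## The simulation study

Five experiment arms compare the heuristic with alternative policies.
Every arm simulates contributor genotypes from known databases under
Hardy–Weinberg and linkage equilibria and records
`diff_ban = heuristic − comparator`; a simulation is conservative iff
`diff_ban <= 0` (exact ties count as conservative, matching the
convention that only strictly positive differences are failures).

1. **One contributor** (`run_experiment_single`): Q simulated from each
   database in turn; comparator is the minimum WoE over the other four
   databases at $\theta = 0$.
2. **Perturbed ancestry** (`run_experiment_fst`): Q simulated from
   frequencies that differ from the base database by Fst of 0.01, 0.02
   or 0.03 — a fresh Balding–Nichols Dirichlet draw (parameters
   $p(1-F)/F$) per profile per locus — then analysed with the
   unperturbed base database.  Drawing per profile rather than once per
   batch models each simulated Q as coming from its own subpopulation;
   the alternative (a single shared subpopulation) would induce
   correlated deviations across the batch and a less demanding test.
3. **Known second contributor** (`run_experiment_two_known`): all 25
   ordered database pairs for (Q, K); comparator as in arm 1, with K's
   profile used in every analysis.
4. **Unknown second contributor, three comparators**
   (`run_experiment_two_unknown`): the same simulation design with U's
   profile withheld.  Comparators: (a) correct databases for X and U —
   identical to the heuristic on the 5 diagonal pairs, hence a
   difference of exactly 0 there; (b) minimum over the four alternatives
   for X with U's correct database; (c) minimum over the four
   alternatives used for both X and U.  "Correct database for X" means
   the database Q was simulated from, since X replaces Q under Hd.
   Whenever an assignment happens to use the database of Q (e.g. for U
   on diagonal pairs under comparator (a) or (b)), the $\theta = 0.03$
   rule applies to it, because the policy is triggered by the database
   choice, not by the comparator's role.

Ordered pairs (including the diagonal) are used for the two-contributor
arms: 25 datasets from 5 databases.

### Synthetic database families

The real five-population frequency data behind this design are not
redistributable, so `generate_family()` builds synthetic families with
the statistical structure the study needs: per locus, ancestral
frequencies from a symmetric Dirichlet(1) (heavy on mid-frequency
alleles, like real STR panels), population frequencies from the
Balding–Nichols Dirichlet around them at each population's F, and counts
drawn multinomially at the panel's per-locus sample sizes (from a few
hundred allele observations at SE33 in the smallest database to nearly
7000 at the most-typed loci in the largest, reproducing the spread of
database sampling noise).  `estimate_fst()` verifies parameter recovery:
with 16 loci and 10 alleles per locus the moment estimate lands within
25% of the generating value.

What the generator does *not* emulate: real STR allele ladders and their
skewed frequency spectra, mutation structure, within-database departures
from Hardy–Weinberg, and relatedness.  Passing the study on synthetic
families therefore establishes the *policy's* behaviour under the
model's assumptions at realistic differentiation and sample sizes, not
the numerical WoE means of any real population panel — those depend on
the actual frequency data.

### Problem sizes and runtime

The packaged study runs 2000 simulations per cell (per database for the
one-contributor arms; per ordered pair for the two-contributor arms),
about 116&nbsp;000 simulated CSPs and 860&nbsp;000 likelihood-ratio
evaluations, in five to ten minutes on one core.  The original-scale
design (10&nbsp;000 per cell for one-contributor arms, 1000 per pair)
is available by raising `n_per_cell`.

```{r, eval = FALSE}
fam <- generate_family(default_family_spec(
  n_alleles = 10, fst = c(0.01, 0.02, 0.03, 0.04, 0.05), seed = 1))
study <- run_conservativeness_study(fam, n_per_cell = 2000, seed = 1001)
summary(study$two_unknown)
```

## Numerical and design choices

* **Tunable parameters.**  `theta` (dimensionless, default 0.03): the
  policy coancestry coefficient; larger is more conservative.
  Alternatives use `theta = 0` — taking a minimum over databases already
  biases toward the defence, so stacking a further positive theta there
  would double-count caution.  `fst` in the generator (default 0.02,
  range 0.01–0.05 in the study): between-population differentiation,
  bracketing worldwide subpopulation-versus-continental estimates.
  Tail thresholds for summaries default to 0, 1 and 2 bans.
* **Ties and determinism.**  The minimum over alternative databases
  breaks ties in favour of the first database in list order; genotype
  enumeration uses a fixed lexicographic order; every experiment seeds
  R's Mersenne–Twister stream once and is bit-reproducible.  Simulation
  randomness is drawn from one sequential stream per experiment; the
  study derives per-arm seeds from its master seed by fixed offsets.
* **Degenerate inputs.**  Single-allele loci, homozygous contributors,
  alleles absent from an analysis database and loci where Hp admits a
  single genotype are all exercised in the test suite; an empty
  admissible genotype set under either hypothesis is an error (it would
  mean the hypothesis cannot explain the CSP without dropout).
* **Tolerances.**  Oracle comparisons (exhaustive ordered-pair
  enumeration) use a relative tolerance of 1e-9; normalisation
  identities 1e-12.

## Known limitations

* No dropout, dropin, peak heights or mixture proportions: the model is
  the discrete no-error idealisation, so results say nothing about
  low-template casework.
* At most two contributors; the enumeration approach scales poorly
  beyond that.
* No relatedness between Q and X, and no theta estimation — the policy
  deliberately uses one fixed, generous value.
* The conservativeness fractions reported by the study are properties of
  synthetic families; absolute WoE means for real populations require
  the corresponding real frequency databases.
* Tail behaviour is family-specific.  The *fraction* of conservative
  simulations is stable across families, but the *magnitude* of the
  rare non-conservative differences depends on how discordant allele
  frequencies can get between databases.  Symmetric-Dirichlet ancestral
  frequencies put more mass on alleles that are rare in one population
  yet common in another than real, ladder-binned STR panels do, and the
  worst cases concentrate where the correct database for U coincides
  with Q's while X is forced onto an alternative: there the heuristic's
  advantage rests entirely on Q's alleles being no rarer in Q's own
  database, which database sampling noise at small loci occasionally
  violates.
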