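---
title: "Integrating transcriptomes into genome-scale metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating transcriptomes into genome-scale metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemtx)
```

## The model and its assumptions

`gemtx` sits on the standard constraint-based modelling stack. A metabolic
network with $m$ metabolites and $n$ reactions is summarised by its
stoichiometric matrix $S \in \mathbb{R}^{m \times n}$; the steady-state
assumption $Sv = 0$ together with flux bounds $lb \le v \le ub$
(mmol g$^{-1}$ h$^{-1}$) defines the feasible flux space. Flux balance
analysis (FBA) maximises the biomass reaction's flux over that space; flux
variability analysis (FVA) reports, per reaction, the minimal and maximal
flux attainable while the biomass flux is held at a fraction
$f \in [0, 1]$ of its optimum (default $f = 1$).

Transcriptome integration rests on two further assumptions:

* **GPR propagation.** A reaction's catalytic capacity is summarised from
  the expression of the genes in its gene–protein–reaction rule. `and`
  (enzyme complex: the scarcest subunit limits) is reduced by minimum or
  geometric mean; `or` (isozymes: alternatives add or the best dominates)
  by maximum or sum.
* **Expression caps flux.** The mapped value $v_g$ of a reaction is used as
  a *magnitude cap*: $ub \leftarrow \min(ub, v_g)$ in the forward
  direction, $lb \leftarrow \max(lb, -v_g)$ in the backward direction.
  Caps only ever tighten bounds. Expression units are used verbatim as
  flux units — there is no biologically principled conversion factor, so
  absolute growth values of a capped model are not physical predictions;
  comparisons between phenotypes processed identically are the intended
  read-out. An optional linear `scale` factor (default 1.0) is exposed for
  users who calibrate one.

## Thresholding: who counts as expressed?

All three approaches partition the genes of one sample into *expressed*
and *suppressed*; comparisons are strict ("above" means $>$, so a value
exactly at a threshold is not above it, and the two LT2 boundaries are
inclusive to the middle zone).

* **GT1** — one global cutoff $T$: expressed iff value $> T$.
* **LT1** — global $T$ plus per-gene local thresholds: value $\le T$ is
  suppressed outright; above $T$ the gene must also beat its local
  threshold. A gene above $T$ with no computable local threshold keeps the
  global decision (expressed).
* **LT2** — lower and upper globals $T_L \le T_U$: above $T_U$ expressed,
  below $T_L$ suppressed, the middle zone is decided by the local
  threshold, and a middle-zone gene without one is conservatively
  suppressed (an uncorroborated intermediate signal is not treated as
  evidence of activity).

A local threshold is the arithmetic mean of the gene's expression across
the replicate samples of the *same* phenotype in which it was measured; at
least two samples are required, otherwise there is no between-sample
signal and only GT1 is meaningful. Locals are computed per phenotype, not
across the whole run, so each condition is judged against its own
replicate structure.

Global cutoffs may be given exactly (expression units) or as a percentile
in $[0, 100]$ of the *pooled* expression values of every loaded sample
(zeros included), so one run resolves to one pair of global numbers.
Percentiles interpolate linearly between closest ranks inclusive of the
extremes (`stats::quantile` type 7); dialects differ on this, so the
choice is stated here and pinned by tests (the median of seven values is
the fourth order statistic).

## GPR evaluation details

Rules are parsed with `and` binding tighter than `or`, case-insensitive
keywords, and full recursion through parentheses. Operator runs at one
syntactic level form a single n-ary node (`a and b and c` has three
children), but parenthesised sub-rules keep their own node. This matters
because the geometric mean is **not** associative:
$\mathrm{GM}(a, \mathrm{GM}(b, c)) = a^{1/2} b^{1/4} c^{1/4} \ne (abc)^{1/3}$.
Evaluation therefore follows the rule text as written, which is the only
semantics under which an independent recursive evaluator and this package
agree on arbitrary nesting; MIN, MAX and SUM are associative and
unaffected. A geometric mean with a zero operand is 0 (the limit of the
formula); no epsilon is injected. Duplicate gene ids within a node are
kept as written, which affects SUM.

Genes without a measurement are governed by `missing_policy`: the default
`"skip"` drops undefined operands (an unmeasured isozyme should not
nullify a reaction whose other isozyme was measured), while `"undefined"`
propagates any gap to the whole rule. A node whose operands are all
undefined is undefined, and reactions with no GPR are never constrained by
expression.

## Constraining options

Starting from the medium-adjusted model (listed exchange bounds applied;
optionally every unlisted exchange's uptake closed):

* **IRREVERSIBLE_ONLY** caps irreversible and backward-irreversible
  reactions in their oriented direction; reversible reactions are left
  alone.
* **ALL_REACTIONS** additionally caps reversible reactions in both
  directions: bounds become $(\max(lb, -v_g), \min(ub, v_g))$.
* **NONESSENTIAL_DELETION** knocks out suppressed genes, but only those
  whose deletion provably does not affect growth: the single-gene-deletion
  growth ratio (deletion-strain FBA optimum over wild-type optimum) must
  equal 1. The test is cumulative — each candidate is evaluated on top of
  the deletions already accepted — so a pair of suppressed isozymes cannot
  both slip through one at a time. Essential suppressed genes are kept and
  audited as `skipped_essential`. Expression caps are then applied as in
  ALL_REACTIONS to the reactions that remain open (so a kept-but-suppressed
  gene still caps its reaction at its low expression value).
* **MEET_MIN_GROWTH** protects the growth optimum from over-aggressive
  caps. An auxiliary model carrying only the medium bounds and the
  non-essential deletions fixes the growth optimum $\mu^\*$; each
  reaction's *minimum flux requirement* is the smallest flux magnitude it
  can carry in any optimal steady state (from the FVA range $[a, b]$ at
  fixed $\mu^\*$: 0 if $a \le 0 \le b$, else $\min(|a|, |b|)$). A cap is
  applied only where the mapped value meets that requirement; otherwise it
  is skipped and audited as `skipped_min_growth`. The "minimum growth
  requirement" is deliberately read as *requirement at the fixed growth
  optimum*: literally minimising biomass flux would trivially return 0 for
  almost every reaction and constrain nothing, so the fixed-optimum FVA
  reading is the one under which the option does useful work. This
  interpretation is stated prominently because it is a genuine design
  choice. Requirements use flux magnitude, so backward-irreversible
  reactions are treated symmetrically.

Every bound change carries an audit record (reaction, old bounds, new
bounds, cause ∈ medium / expression_bound / gene_deletion /
skipped_min_growth / skipped_essential), which downstream tasks rely on to
distinguish expression-derived effects from structural ones. Blocked
reactions keep their stoichiometry — bounds go to $(0, 0)$ but nothing is
pruned from the network.

## Analysis tasks

*Non-optimization* (no model, no LP): high/low gene lists straight from a
classification; and cross-phenotype comparison of expression, pairwise
against the first-listed dataset over a shared gene universe, with ratio
$A/B$, a pseudo-count of 1 read added to both sides when either is 0 (so
ratios stay finite while preserving order), and a fold threshold
`min_fold` (default 1: any difference counts, since no universal fold
cutoff exists).

*Post-optimization* (context model + FVA):

* **Non-flux reactions** — FVA range within $10^{-6}$ of zero *and* an
  expression-derived audit cause. The cause filter keeps structurally
  blocked reactions of the source model out of the report: the claim made
  is "silenced by low expression", not "cannot carry flux".
* **Rate-limiting reactions** — the applied expression cap equals the FVA
  extreme within $10^{-6}$ (upper bound vs FVA max; lower bound vs FVA min
  for backward-irreversible reactions): the transcriptome, not the
  network, limits the flux.
* **Flux shifts** — per reaction, the ratios of FVA minima and maxima
  between two phenotypes are both reported (the informative one depends on
  the reaction's directionality, so neither is privileged). The
  up/down/unchanged call uses the ratio of flux-range magnitudes
  $\max(|min|, |max|)$ per side, which makes the comparison anti-symmetric
  (swapping phenotypes inverts ratios and flips calls) even for reversible
  reactions with negative extrema. A range magnitude below $10^{-6}$ on
  one side only is reported as `new`/`lost` with `NA` sentinel ratios.

## Numerical choices

No linear-programming backend is assumed: the package carries a dense
two-phase primal simplex with Bland's anti-cycling rule (entering variable
= lowest eligible index; leaving = lowest basic index among ratio ties, so
degenerate vertices cannot cycle and results are deterministic). Pivot and
feasibility tolerance is $10^{-9}$; reported invariants (mass balance,
FVA-sandwiches-FBA) are asserted at $10^{-6}$. Variable bounds must be
finite, which constraint-based models satisfy by convention (±1000
defaults). A dense tableau is exact and fast for the tens-of-reactions
models the package targets; it is *not* suited to genome-scale networks
with thousands of reactions, where an industrial sparse solver is the
right tool. At degenerate optima only the objective value is unique; FBA
flux vectors are one optimal vertex, and FVA is the instrument for
alternate-optimum questions. Infeasibility and unboundedness are reported
as statuses, never as silent zeros.

## The synthetic-data generators

`generate_toy_model()` emits a linear pathway
`EX_S → M1 → … → BIOMASS` with unit stoichiometry, optional redundant
parallel branches (same start and end metabolites), an isozyme-gated
reaction (`"gA or gB"`) and a complex-gated one (`"gC and gD"`). Its FBA
optimum is the uptake bound's magnitude (10 by default), which every hand
LP in the tests exploits. `generate_transcriptome()` draws per-gene values
from one of two log-normal components — the standard shape for sequencing
read counts — according to planted high/low labels, independently per
replicate, reproducibly under a seed, with defaults meanlog 3 and 7
(sdlog 0.5): medians of roughly 20 and 1100 reads, the kind of separation
between background transcription and active expression seen in RNA-seq
count data.

What these fixtures deliberately do not emulate: genome-scale network
size, realistic biomass composition, correlated expression between genes,
overdispersion or zero inflation of counts, or any particular organism's
biology. Passing tests therefore certify the *algorithms* — threshold
logic, GPR semantics, LP correctness, audit bookkeeping — not the
biological fidelity of any particular yeast or bacterial analysis. Test
problem sizes are chosen to keep the whole suite fast: chains of 2–5
reactions with up to 2 parallel branches, 100-gene transcriptomes with 3
replicates, and 1000 random GPR trees of depth ≤ 5 over ≤ 12 genes for the
oracle-equivalence property.

## Conventions and degenerate inputs

* Sheet (or CSV file) names encode `<phenotype>_<sample>`, split on the
  *last* underscore; a name with no underscore is a phenotype with a
  single anonymous sample. Gene ids are matched case-sensitively, exactly
  as spelled in the model; no alias resolution is attempted.
* Duplicate genes within one sample, negative or non-numeric expression
  values, empty sheets, medium rows with `lower > upper`, and GPRs
  referencing undeclared genes are all hard errors with the offending
  element named.
* Reports are written as one CSV per sheet with deterministic column
  order. xlsx is accepted on input (via `readxl`); output is CSV only.
* Manual bounds supplied on the command line override medium-file values
  for the same reaction.

## Known limitations

Dense LP limits model size (by design); expression units pass through to
flux bounds unconverted; `.mat` models are not read (SBML + JSON + tabular
cover the practical formats without binary coupling); no reaction pruning,
pathway enrichment, MILP-based integration (iMAT/MADE-style), pFBA, MOMA
or sampling. Cross-phenotype comparisons beyond two datasets are emitted
pairwise against the first-listed dataset; no n-way statistic is defined.
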