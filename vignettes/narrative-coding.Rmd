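---
title: "Quantifying hand-coded streams of consciousness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hand-coded streams of consciousness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenostream)
```

## The problem

A phenomenological text is a first-person verbal report that expresses
ongoing conscious experience at the moment of speaking or writing —
interior monologs, think-aloud transcripts, journal entries. Such texts
can be treated as data for consciousness research once they are coded:
broken into segments that readers perceive as units, labeled with the
mental categories each segment expresses, and linked where one mental
state appears to generate the next. All of that coding is done **by
hand** by panels of human judges; automated sentiment or language models
cannot yet attribute specific mental states with the accuracy a reader
can. What hand coding needs instead is statistical discipline: agreement
across independent judges, and explicit significance criteria for every
attribution. `phenostream` supplies that discipline — it stores,
validates, analyzes and renders human codings; it never produces them.

The package covers three stages:

1. **Consensus segmentation.** Each judge marks, for every candidate
   boundary of a text, whether a thematic break occurs there. The
   agreement index of a boundary is the plain fraction of judges marking
   it. The text is split at every boundary whose index is *strictly
   greater* than a threshold; by default the threshold is the unrounded
   mean index over all candidate boundaries.

2. **Attribution statistics.** For each consensus segment, judges
   attribute zero or more mental categories (the seven broad textbook
   terms: sensation, perception, emotion, thought, image, recall,
   intention). With $n_s$ the number of judges who recognized segment
   $s$ and $k_{sk}$ of them attributing category $k$, the cell
   proportion is $k_{sk}/n_s$. Two one-sided exact binomial tests
   against a null attribution probability $p_0$ flag each cell:
   *high* when $P(X \ge k_{sk}) < \alpha$ and *low* when
   $P(X \le k_{sk}) < \alpha$, with $X \sim \mathrm{Bin}(n_s, p_0)$.
   Segments with two or more high flags are *composite states* (several
   mental factors bound into one state of consciousness); segments with
   none received no reliable content attribution at all.

3. **Stream model.** A coded stream — one entry per segment, each with
   one or more contents in a category lane, plus annotator-asserted
   causal links between consecutive segments — is rendered as an open
   Petri-net-style graph: contents are places on a time axis (one
   arbitrary unit per segment), simultaneous contents of a segment are
   bound into a single state by a vertical line, causal links are arcs
   with arrow tips, and maximal runs of causally linked segments form
   *micro-episodes*. The model exports to Graphviz DOT and to PNML
   (place/transition nets).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | `"mean"` | consensus cut on agreement indices; a number in [0, 1] fixes it instead |
| `p0` | 0.5 | null attribution probability per judge (attribute vs not) |
| `alpha` | 0.01 | per-cell significance level, each side |
| `correction` | `"none"` | optional Bonferroni over the S × K cells |
| `time_weight` | `"unit"` | x-spacing of the stream diagram; `"words"`/`"chars"` rescale by segment length |

The threshold comparison always uses the *unrounded* mean: rounding is
presentation, not computation. "Above the threshold" is strict, so a
degenerate panel that marks every boundary equally yields a single
segment rather than an arbitrary split. Both choices are invisible on
the packaged journal data (no index equals the mean there), but they fix
the behavior on edge cases. A fixed threshold of 0.5 ("more than half
the judges") is a documented alternative to `"mean"`; the two happen to
agree on the packaged data, and `"mean"` is the default because it
adapts to panels that mark liberally or conservatively.

The null $p_0 = 0.5$ treats each judge's attribution as a coin flip
between attributing and not attributing a given category; $1/K$ (one
category drawn from $K$) is a documented alternative via the `p0`
argument. Published tables of this kind do not always state their null,
and their flag patterns need not be reproducible from any single choice;
the package therefore keeps externally printed flags as verbatim
metadata (`source = "printed"`) alongside computed flags
(`source = "computed"`) and reports cell-by-cell differences with
`flag_diff()` instead of force-fitting either. No multiple-testing
correction is applied by default because the per-cell level is the
convention of the tables this reproduces; `correction = "bonferroni"`
is available.

The per-cell denominator is $n_s$, the judges who recognized the
segment, not the full panel size — a judge who never identified a
segment cannot testify about its content.

## Conventions and numerical choices

* Character offsets are 1-based and inclusive, matching R's `substr()`.
  Tokens are maximal non-whitespace runs.
* A candidate boundary at position $p$ is the gap after token $p$;
  $p = n_{\mathrm{tokens}}$ denotes the text terminus. The terminus is a
  legal candidate (panels are routinely asked about the end of a final
  clause) but never splits: a partition with $b$ kept internal
  boundaries has $b + 1$ segments.
* Candidate boundaries of a text that an agreement vector does not cover
  count as index 0 — they are simply never kept.
* Exact binomial tails are computed by direct summation of binomial pmf
  terms; no approximation, no continuity correction. For $\alpha \le
  0.5$ a cell can never be flagged both high and low.
* The stream model is deterministic: places are ordered by time, then by
  the scheme's lane order, then label, so DOT and PNML exports are
  byte-identical across runs. Petri nets are bipartite, so each causal
  link from the state at $t$ to the state at $t+1$ becomes an explicit
  transition with arcs from all places at $t$ and to all places at
  $t+1$; the open diagram's arrow tips play this transition role
  graphically. Within an episode, links are chained (each segment to its
  successor); the coding format carries no longer-range links.
* Two contents can share one lane in one segment (e.g. two emotion words
  bound into a single state); the layout offsets such co-located places
  vertically.

## The packaged datasets

`load_fixture("unamuno_journal")` reconstructs a 107-token Spanish
journal excerpt evaluated by a panel of sixteen psychology students: 16
candidate boundaries (the printed line breaks, the last being the
terminus) with their published agreement indices, and a 9-segment ×
7-category attribution table with published proportions and
significance flags. Judge-level marks were never published, so the
fixture reconstructs them deterministically: a boundary with index $i$
gets marks from judges $1..\mathrm{round}(16\,i)$. Column sums — the
only thing any statistic here consumes — are unaffected by which judges
carry the marks. Attribution counts are likewise
$\mathrm{round}(p \cdot n_s)$ (half away from zero). Cells whose printed
proportion cannot be written as $k/n_s$ to within half of the printed
two-decimal precision (three cells, e.g. 0.90 with $n=16$) are stored at
the nearest integer count and listed in the bundle's `discrepancies`
table — printed values are treated as ground truth to be reported
against, never silently corrected. One printed index (0.934) is not a
multiple of 1/16 but rounds to 15/16 within that same slack.

```{r unamuno}
fx <- load_fixture("unamuno_journal")
v <- boundary_agreement(fx$segmentation)
mean_agreement(v)
res <- consensus_segments(fx$text, v, threshold = "mean")
res
fx$discrepancies
```

`load_fixture("joyce_penelope")` carries a classical 30-sentence
interior-monolog excerpt coded into four lanes (S sensations, E
emotions, T thoughts including recollections and plans, I mental images
including fantasies), with 40 contents in total and causal links broken
at six positions, which partitions the stream into seven
micro-episodes. The fine label → lane mapping ships as an editable
table (`joyce_label_map()`); the anaphoric label `"same"` (a content
carried over from the previous segment) is deliberately unmapped and
resolved in the stored coding itself.

```{r joyce}
jf <- load_fixture("joyce_penelope")
model <- build_stream(jf$stream)
model
model$episodes
plot(model)
```

## The simulator: what it emulates and what it does not

`simulate_segmentation_panel()` and `simulate_attribution_panel()`
generate panels of independent, exchangeable judges: marks are
independent Bernoulli draws per boundary, and attribution is a two-stage
draw (recognize the segment, then attribute each category). This is
exactly the statistical structure the agreement index and the exact test
assume, which makes the simulator the right tool for calibrating them —
type-I error of the flags under a true null, power along a grid of true
attribution probabilities (`power_curve()`), and the sampling noise of
agreement indices at a given panel size. With 16 judges, the high flag
at $\alpha = 0.01$ against $p_0 = 0.5$ requires 14 of 16 attributions;
with only 2 judges no outcome can reach significance at all —
`power_curve(2, 0.5, 0.01, ...)` is identically zero, a useful reminder
that tiny panels cannot support per-cell exact tests.

What the simulator does **not** model: judge bias or leniency
differences, correlation between neighboring boundaries or related
categories, and any semantic structure of the text. Passing calibration
tests therefore shows the statistics behave as designed under the
exchangeable-panel model; it does not show that a particular human
panel satisfies that model. Seeds are mandatory; identical
specifications yield byte-identical protocol files.

Test and calibration problem sizes (10,000 simulated null cells, panels
up to 1,000 judges, random streams up to 50 segments) were chosen so
that Monte-Carlo bounds are sharp at three standard errors while the
whole suite runs in seconds.

## Known limitations

* Translations are stored and displayed, never analyzed.
* Causal links are stored annotator judgments; nothing infers causality
  from text, and the coding format only expresses links between
  consecutive segments.
* No chance-corrected agreement coefficients (kappa, Krippendorff's
  alpha) and no probabilistic segmentation models — the implemented
  procedure is a plain fraction with a mean threshold, and extensions
  belong in analysis code, not in this toolkit.
* The stream model does not simulate token firing or reachability; the
  Petri-net form is a representation device.
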