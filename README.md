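# phenostream

Quantitative analysis of hand-coded phenomenological texts — first-person
verbal reports of ongoing conscious experience such as interior monologs
and journal entries. Research panels code these texts by hand: judges mark
thematic boundaries, attribute mental categories to the resulting
segments, and assert causal links between consecutive mental states.
`phenostream` is the statistical and modeling toolkit around that human
coding. It is aimed at consciousness researchers, neurophenomenologists
and anyone running inter-observer annotation studies on discourse.

## What it computes

**Consensus segmentation.** For a panel of `J` judges marking candidate
boundaries, the agreement index of boundary `b` is the fraction of judges
marking it. The text splits at every boundary whose index is strictly
greater than a threshold — by default the unrounded mean index over all
candidates:

    index_b = (# judges marking b) / J,     keep b  ⇔  index_b > mean(index)

**Attribution flagging.** With `n_s` judges recognizing segment `s` and
`k` of them attributing category `c`, the cell proportion is `k / n_s`,
and two one-sided exact binomial tests against a null attribution
probability `p0` (default 0.5) flag the cell at level `alpha` (default
0.01):

    high  ⇔  P(X ≥ k) < alpha,    low  ⇔  P(X ≤ k) < alpha,    X ~ Bin(n_s, p0)

Segments with ≥ 2 high flags are *composite states*; segments with none
received no significant content attribution.

**Stream model.** A coded stream becomes a Petri-net-style graph:
contents are places on a time axis (one unit per segment), simultaneous
contents are bound into one state, annotator-asserted causal links are
arcs, and maximal causally linked runs are *micro-episodes*. Exports to
Graphviz DOT and PNML; plots with base graphics.

**Panel simulation.** Seeded generators for segmentation and attribution
panels of independent judges, for calibrating the threshold rule and the
exact test (type-I error, power curves).

## Worked example

Two classical annotation datasets ship with the package. The journal
excerpt was segmented by sixteen judges over 16 candidate boundaries and
coded into seven mental categories:

```r
library(phenostream)

fx <- load_fixture("unamuno_journal")
v  <- boundary_agreement(fx$segmentation)
round(mean_agreement(v), 4)
#> [1] 0.6016

consensus_segments(fx$text, v, threshold = "mean")
#> <consensus_result 'unamuno_journal': threshold 0.6016 (mean), 9 kept boundaries, 9 segments>
```

The mean agreement displays as 0.60 and cuts the text into the nine
published segments. The attribution table reproduces cell by cell —
e.g. all 16 judges saw an emotion in segment 8, and 13 of 16 saw a
thought in segment 4:

```r
pm <- proportion_matrix(fx$attribution)
sprintf("%.2f", pm$proportions[8, "Em"])   # "1.00"
sprintf("%.2f", pm$proportions[4, "Th"])   # "0.81"

fl <- printed_flag_matrix(fx$attribution)
composite_states(fl)   # 1 7 8 9  (states binding several categories)
empty_segments(fl)     # 2 5 6    (no significant content attribution)
```

The interior-monolog excerpt is a 30-sentence coded stream over four
lanes (S/E/T/I) whose causality breaks partition it into seven
micro-episodes:

```r
jf <- load_fixture("joyce_penelope")
model <- build_stream(jf$stream)
model
#> <stream_model 'joyce_penelope': 30 segments, 40 places, 10 bindings, 23 causal arcs, 7 episodes>
model$episodes
#>   start end
#> 1     1   4
#> 2     5  13
#> 3    14  16
#> 4    17  17
#> 5    18  22
#> 6    23  26
#> 7    27  30
plot(model)                        # stream diagram with episode bands
cat(to_dot(model))                 # Graphviz DOT
cat(to_pnml(model))                # PNML place/transition net
```

A command-line front-end wraps the same functions
(`inst/exec/phenostream`): subcommands `segment`, `attribute`, `stream`,
`simulate`, `run`, `fixtures`.

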