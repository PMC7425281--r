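---
title: "Inferring and validating proximity-based social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and validating proximity-based social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btnet)
```

## The problem

Bluetooth-style proximity scanning produces a log of ordered detections —
"in scan period S13 of day 2, the device of pupil *i* saw the device of
pupil *j*". Turning such a log into a social network requires decisions
that are usually made ad hoc: how strong must the co-detection signal be
before a pair counts as connected, how much data is enough, and should the
network be directed? `btnet` treats these as an optimization problem:
where a sociometric reference network exists, every combination of the
decisions is evaluated against it, and the best-supported network is
selected by an explicit, reproducible rule.

## The weight model

The tie strength between nodes $i$ and $j$ is

$$w_{ij} = \frac{c_{ij} + c_{ji} + \alpha}{s_i + s_j + \beta},$$

where $c_{ij}$ is the number of scan periods in which $i$ detected $j$ and
$s_i$ the number of *successful* scan periods of $i$. Two modelling
commitments sit inside these symbols:

* **One detection per ordered pair per slot.** Scan logs are deduplicated
  on (scanner, detected, wave, day, period), which guarantees
  $c_{ij} \le s_i$ and hence $w_{ij} < 1$ whenever $\beta \ge 1$.
* **A successful scan period of $i$ is a slot in which $i$ logged at least
  one detection.** Empty scan attempts are unobservable in the scanner →
  detected schema, so genuinely silent slots cannot be distinguished from
  slots in which the device did not scan. This slightly overstates the
  per-slot detection rate for poorly connected nodes (they are only
  "successful" when they saw someone); the long-run convergence test in
  the suite therefore uses a densely tied fixture where the effect is
  negligible.

The smoothing pair $(\alpha, \beta)$ exists because the *raw* ratio assigns
identical weight 1 to a pair detected in 44 of 44 combined scans and a
pair detected in 5 of 5. The defaults $\alpha = 0$, $\beta = 1$ bias all
weights toward zero, more strongly at low scan activity, which orders
those two pairs sensibly (44/45 vs 5/6). Both parameters are exposed;
$\beta \ge 1$ also makes the weight well-defined for node pairs that never
scanned. With $\alpha = \beta = 0$ and no scans the weight is a hard error,
never a silent `NaN`.

The weight is symmetric by construction, so the *directed* connection type
simply carries two opposite arcs of equal weight; it differs from the
undirected type only through the reference network it is compared with
(nominations are genuinely directional) and the doubled pair universe.

## The reference (ground-truth) networks

Directed nomination weights are the count of distinct items (of six
sociometric questions) on which $i$ nominated $j$, divided by 6; repeated
nominations of the same peer on the same item count once, since each item
is a binary instrument. The undirected weight sums both directions and
divides by 12. An edge exists wherever the weight is positive — the
reference is never thresholded, and an undirected edge does *not* require
mutual nomination (the sum formula admits one-sided ties). Binary
friendship matrices are read as unit-weight networks, undirected when
symmetric.

## The search and its tie-breaks

The grid crosses edge-weight thresholds with *cumulative prefix* windows
over days and over eligible scan periods: (D1), (D1–D2), …, and (S1),
(S1–S2), …. Prefixes, not arbitrary subsets, keep the search
interpretable ("how many days of collection buy how much accuracy") and
the candidate count linear rather than exponential in the schedule. The
default thresholds are 0.01–0.60 in steps of 0.01: 60 values, with 0
reserved for the baseline scenario. The 0.6 cap reflects the isolation
diagnostic — beyond it, thresholding mostly disconnects nodes
(`isolated_fraction()` grows monotonically in the threshold) — and the
default window depth of 16 scan periods reflects a typical school-hours
schedule after the ≥ 30-observations-per-period data-quality filter. With
five days this yields 4800 candidates per connection type.

Thresholding is strict (`w > threshold`), and the participation filter is
strict as well (a class at exactly the 60% participation threshold fails).
Scoring uses classification accuracy over the full pair universe — all
$N(N-1)$ ordered or $N(N-1)/2$ unordered pairs of the *survey roster*,
including participants who never logged a scan, because the quantity of
interest is the class network, not the subgraph of active devices. For
sparse references (density far below one half) accuracy saturates at the
share of non-edges and the Matthews correlation coefficient is the
appropriate score; its zero-denominator case (any empty confusion margin)
is defined as 0, the standard convention for a degenerate predictor.

Ties are frequent: many parameter tuples produce identical networks. The
selection rule is argmax metric, then fewest scan records used, then
fewest days, then fewest scan periods, then the lexicographically smallest
(weight, days, scans) tuple. The last step is ours: the preceding rules
can still tie, and a fitting procedure must be a function of its inputs.
Distinct-value accounting rounds the metric to 4 decimals (the reporting
precision) before counting; distinct networks are counted by canonical
edge-set fingerprint, and neither count bounds the other.

## Structural comparison battery

All structural metrics operate on the binarized graph. Density counts
isolated roster nodes in $N$. Assortativity is Newman's discrete
coefficient on the gender mixing matrix; a graph whose edge endpoints all
carry one category has no defined coefficient and is reported `NA` rather
than 1. Centralization follows Freeman's form $\sum_v (c_{max} - c_v)/H$
with the star-calibrated normalizers: $(n-1)(n-2)$ for undirected degree,
$(n-1)^2$ for in-degree, $(n-1)(n-2)/(2n-3)$ for normalized closeness; for
undirected networks plain degree is used where a directed analysis would
use in-degree. Closeness on disconnected graphs — routine after
thresholding — uses the Wasserman–Faust convention: each node's closeness
is computed within its reachable set and scaled by
$(\text{reachable}-1)/(n-1)$, so isolates contribute 0 instead of breaking
the metric. Eigenvector centrality is computed by power iteration on
$A + I$ (same principal eigenvector as $A$, but immune to the sign-flip
oscillation on bipartite graphs such as stars) to tolerance $10^{-9}$
with at most 10,000 iterations, normalized to maximum 1; non-convergence
is an error that reports the iteration count. The comparison report adds
the Spearman rank correlation of the two degree sequences, which is `NA`
when a sequence is constant (a clique has no ranking to correlate).

## The synthetic study generator

The generator emulates the features of proximity field studies that the
validation machinery must survive:

* a gendered class roster (default 15 pupils, 53% girls) with planted
  gender homophily (default 0.7, the probability a nomination stays
  within gender) and hub pupils (default 3, nominated $1 + 2$ times as
  readily) — so reference networks show positive assortativity and
  hub-driven centralization;
* nomination counts per tie as $\min(6, 1 + \text{Poisson}(1.5))$,
  matching the 1–6 item range;
* a five-day wave with a 07:00–19:00 quarter-hour schedule (48 slots/day;
  a full day at 5-minute cadence gives 288), uneven participation
  (default: a node scans in 70% of slots), detection probability 0.8 for
  tied co-present pairs less a 10% miss rate, and a 5% per-slot
  false-positive rate for untied pairs. The tie density default
  (`p_tie = 0.5`) puts the directed reference density near 0.5, the range
  typical of close-knit school classes.

Everything is driven by one seed; the scan-log stream is derived
deterministically from it so ground truth and log are independently
reproducible. What the generator does **not** model: correlated
co-location noise (a shared classroom makes false positives dependent),
time-of-day structure in participation, device dropout, RSSI, or
nomination errors in the reference itself. Passing tests on this
generator therefore demonstrate the machinery's correctness and its
behavior under independent noise — not that any particular field dataset
will reach a given accuracy.

Two properties of the generator anchor the test suite: in the noiseless
limit the inferred network at threshold 0 equals the planted network
exactly, and under a 10% false-positive rate the selected threshold is
positive and beats the baseline in at least 90% of seeded replicates —
thresholding demonstrably removes noise rather than signal.

## Problem sizes and runtime

The implementation evaluates each (day, scan) window once as a weight
matrix and sweeps all thresholds over it, so the full 4800-candidate
search on a 15–20 node, five-day log takes a few seconds. The test suite
runs the search at 8–20 nodes, the replicate-based checks at 50 seeded
replicates, the coin-flip MCC calibration at 1000 replicates on 20 nodes,
and the law-of-large-numbers check at 5000 slots on 6 nodes — sizes chosen
so the whole suite completes in about a minute while keeping Monte-Carlo
error well inside the asserted tolerances.

## Known limitations

The method needs a reference network; without one the grid still runs but
nothing anchors the threshold choice. The pair universe assumes a closed
roster — detections of unknown devices are dropped, not modelled. Windows
are prefixes, so "weekend-only" subsets require pre-filtering the log.
And the reference itself is treated as truth although self-reports have
their own error process; disagreement between the two instruments is
reported, not adjudicated.
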