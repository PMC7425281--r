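# btnet — inference and validation of Bluetooth proximity social networks

Proximity scans from phones and wearables are a cheap, unobtrusive way to
observe who spends time near whom. But scan logs are noisy instruments for
social structure: devices miss each other, participation is uneven across
people and hours, and mere co-presence in a corridor is not friendship.
Studies that treat the raw detections as "the network" inherit all of that
noise. `btnet` is for researchers who have both a proximity log and a
sociometric reference (peer nominations or a reported-friendship matrix)
and want to know *which* network the log actually supports — and how far
even the best inferred network strays from the reported one.

## The method

**Edge weights.** For nodes *i*, *j* the tie strength is the
Laplace-smoothed co-detection rate

    w_ij = (num_connections(i,j) + num_connections(j,i) + α) /
           (num_scans(i) + num_scans(j) + β)

where `num_connections(i,j)` counts scan periods in which *i* detected *j*
and `num_scans(i)` counts *i*'s successful scan periods (slots with at
least one detection logged). The defaults α = 0, β = 1 bias weights toward
0, more strongly for pairs with little scan activity, so that a pair seen
in 44 of 44 combined scans outranks one seen in 5 of 5.

**Ground truth.** The directed reference weight is the number of distinct
sociometric items (out of six) on which *i* nominated *j*, divided by 6;
the undirected variant sums both directions and divides by 12. A binary
friendship matrix can stand in for nominations.

**Validation search.** The candidate space is a grid over the edge-weight
threshold (edges kept when `w > threshold`; default 0.01–0.60 in steps of
0.01), cumulative day windows, cumulative scan-period windows, and the
connection type (directed/undirected) — 60 × 5 × 16 = 4800 candidates per
type for a five-day, sixteen-period log. Each candidate is scored against
the reference over *all* node pairs by classification accuracy
`(TP + TN) / (TP + TN + FP + FN)`, or by the Matthews correlation
coefficient when the reference is sparse and the classes imbalanced. The
argmax wins; ties go to the candidate built from fewer scan records, then
fewer days, then fewer scan periods. Everything is judged against the
*baseline* scenario — threshold 0, full window, i.e. no optimization.

**Structural comparison.** Because a high pair-classification score can
hide real structural disagreement, a metric battery (density, Newman
gender assortativity, Freeman degree/closeness centralization, degree and
eigenvector centrality, degree rank correlation) compares the selected
network with the reference.

A seeded simulator generates complete synthetic studies — a gendered class
roster with planted homophily and hub pupils, nomination tables, and noisy
scan logs with configurable participation, detection, miss and
false-positive rates — so the whole pipeline is testable without any field
data.

## Worked example

```r
library(btnet)

cfg <- sim_config(p_false_positive = 0.15, p_detect_edge = 0.55,
                  p_miss = 0.2, p_participate = 0.4, periods = 0:15,
                  seed = 7)
study <- simulate_study(cfg)

fit <- bva(study$log, study$gt_undirected, metric = "accuracy")
summary(fit)
#> Brute-force network validation, metric = accuracy
#>   4800 candidates; metric range [0.2762, 0.8952]
#>   distinct metric values: 66; distinct networks: 1580
#>   1 candidate(s) tied at the optimum
#>   optimal 0.8952 vs baseline 0.7333 (improvement +0.1619)
#>   selected: weight > 0.10, days = 5, scans = 16

compare_sna(sna_report(study$gt_undirected, study$gender),
            sna_report(predict(fit), study$gender))
#> Structural comparison (GT vs inferred):
#>   density                   0.724 /  0.771  (delta +0.048)
#>   assortativity_gender      0.206 /  0.131  (delta -0.075)
#>   centralization_degree     0.154 /  0.099  (delta -0.055)
#>   centralization_closeness  0.192 /  0.128  (delta -0.063)
#>   degree rank correlation  0.850
```

Reading the output: of 4800 candidate networks only 1580 are distinct, and
raw use of the data (the baseline, accuracy 0.73) is beaten by a
thresholded two-thirds-smaller candidate at 0.90 — thresholding removes
false-positive edges. The structural comparison shows the classic residual
bias: the inferred network is slightly denser, less gender-assortative and
less centralized than the planted truth, even at 90% pair accuracy.

`coef(fit)` returns the selected parameters, `predict(fit)` the selected
network, `plot(fit)` the accuracy-versus-threshold profile, and
`fit$results` the full per-candidate table.

A thin command-line wrapper lives in `inst/cli/btnet.R`
(`simulate` / `infer` / `bva` / `sna` subcommands driven by a YAML config);
the R functions `cmd_simulate()`, `cmd_infer()`, `cmd_bva()` and
`cmd_sna()` do the same from R.

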