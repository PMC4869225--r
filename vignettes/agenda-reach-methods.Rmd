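---
title: "Measuring agenda-setting influence in keyword-tracked social streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring agenda-setting influence in keyword-tracked social streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(agendareach)
```

## The measurement problem

Agenda-setting research asks whose concerns shape public discussion. On a
microblogging platform this becomes measurable: track a topic by literal
keywords over a fixed window, record every original post, reply and retweet
that matches, and ask which *kinds* of accounts — private individuals,
non-media organizations, media outlets, policy bodies — reach the largest
audiences, and whether the platform's attention to the topic moves in step
with traditional media coverage.

`agendareach` implements that analysis end to end. This vignette documents
the model behind each stage, the tunable parameters, what the bundled
synthetic generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## Reach model

Each tweet carries four counters. *Deliveries* is the author's follower
count at posting time — the audience the message reaches directly. Each
retweet re-delivers the message to the retweeter's followers, so *retweet
impressions* is the sum of retweeter follower counts over the tweet's
retweet events, and *total impressions* is deliveries plus retweet
impressions. Follower counts are frozen per event: real counts drift, and
freezing is what makes the sums well defined. Replies can optionally be
supplied as additional events and are then accounted identically — the
default accounts only deliveries plus retweet impressions, because reply
audiences are not separately quantifiable from the event stream.

At the contributor level, *impressions* accumulates the deliveries of
everything an account posted during the window (originals, replies, and
its own retweets — each of which delivers to the account's followers), and
*total exposure* adds the retweet impressions its posts attracted. The
amplification multiplier

$$A = \frac{\text{total exposure} - \text{impressions}}{\text{impressions}} + 1$$

is the factor by which retweeting spread the account's content beyond
direct delivery; $A = 1$ means no spread, and $A$ is undefined when
impressions are zero (the package raises an error rather than guessing).
Whether contributor impressions should accumulate over all authored
activity was an open point; per-contributor accumulation is used because
the multiplier is defined per contributor, not per tweet, and the choice
is isolated in `build_contributors()` for sensitivity work.

## Filter cascades

Influence measurement uses deliberately aggressive filtering, and every
filter logs its input and output sizes so attrition is auditable:

1. **Regular keyword tweets** — originals only, with at least one literal
   keyword match. Matching is exact substring, case-sensitive, with no
   Unicode normalization: the tracked keywords are fixed strings, and any
   looser matching policy belongs to the caller's pre-normalization.
2. **Zero-retweet exclusion** — a tweet nobody retweeted exerted no
   second-hand influence.
3. **Best tweet per author** — the tweet with the highest retweet
   impressions. Ties are broken by earliest timestamp, then smallest tweet
   id; the data give no grounds for any particular tie-break, so the
   requirement is only that it be deterministic.
4. **Amplification cut-off** — contributors below $A = 1.2$ are dropped,
   the platform-analytics convention for "spreading conversation well".
   The boundary is kept ($\geq$, not $>$): a contributor at exactly 1.2x
   qualifies.
5. **Above-mean deliveries** — before interaction analysis, retweet events
   are restricted to those delivered *strictly* above the arithmetic mean
   of deliveries. Strictness matters only for values exactly at the mean;
   the strict reading is consistent with the case study's reported counts
   (2,665 of 40,193 retweets above a mean of 2,888.5).

All filters are idempotent, and the cascade's stage counts are monotone
non-increasing — both are enforced by tests.

## Classification and reliability

Account types come from human coding sheets. Reliability of a coding is
quantified by two-rater Cohen's kappa over the items both raters coded:
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_o$ the observed agreement and
$p_e$ the chance agreement from the raters' marginal label frequencies.
The degenerate case where both raters assign a single identical label
makes $p_e = 1$; agreement is then perfect by construction and $\kappa$ is
reported as 1 with a note rather than NaN. Benchmarks follow Fleiss:
below 0.40 poor, 0.40–0.75 (both ends inclusive) intermediate-good, above
0.75 excellent. The source scale prints its bounds without decimal points;
they are read as 0.40 and 0.75, Fleiss's published values.

## Per-type influence tables

For each measure, per-type totals are converted to percentage shares of
the grand total. Three measures are combined: reverse-rank-scaled retweet
impressions, total impressions, and amplification multipliers. Rank
scaling — rank $r$ of $N$ (1 = largest) scores $N - r + 1$ points, ties
sharing the mean of their span — dampens the leverage of extreme outliers
so that one viral tweet cannot dominate the share table; the tie-mean rule
preserves the total score $N(N+1)/2$. "Simple rank scaling" admits other
readings (percentile scores, say); the linear reverse-rank form is the
plainest and is isolated behind `rank_scale()` so alternatives can be
swapped without touching share computation, which is agnostic to the
measure. The cross-measure average is the unweighted mean of the three
percentage shares per type.

Percentages are presented rounded *half-up* to 2 decimal places
(`round_half_up()`), matching how such tables are conventionally printed;
R's default round-half-even would flip some boundary cells. Unrounded
values are retained internally and used for all further arithmetic.

The popularity-vs-influence check is a plain sample Pearson correlation
(deliveries vs retweet impressions; impressions vs amplification): a
near-zero $r$ says widely spread content need not come from widely
followed accounts. No significance test is attached — at these sample
sizes the point estimate is the object of interest, and the package
deliberately attaches no qualitative label to $r$.

## Interaction matrices

Retweeting defines a directed influence relation: the author of the
retweeted message is the *source* of influence, the retweeter the
*target*. The 4×4 matrix counts **distinct (source, retweeter) user
pairs** — interactions between users, not raw events — with self-retweets
excluded; a switch allows raw-event counting. Row shares
(row total / grand total) measure a type's influence as a source, column
shares as a target. The orientation is fixed by reproducing the bundled
case study's individual-row share of 80.46% as a *row* share.

Two cells of the published case table disagree with their own arithmetic
(59.33 vs 59.34, 14.47 vs 14.74 between table and narrative); the package
treats standard rounding of the cell arithmetic as authoritative and
reports 59.33 and 14.47. Likewise the published policy-row cross-measure
average prints 4.03 where its own printed cells average 4.02; the package
reports 4.02. These are reproduction notes, not bugs.

## Trend comparison

Daily mention counts per channel are max-normalized (divided by the series
maximum) so channels of very different volumes share a `[0, 1]` scale; an
all-zero series stays zero with a warning rather than producing NaN. The
original comparison of the two trend lines was visual; the package
replaces it with an explicit, parameter-free-of-randomness procedure:

- a **spike** is a local maximum (at least as large as both neighbours and
  strictly larger than one — so a constant series has no spikes, and a
  flat-topped peak counts once, at its first day) with normalized height
  at least `height` (default 0.3, roughly the smallest bump a reader would
  call a spike on a normalized plot), spikes closer than `min_separation`
  days (default 2) resolved in favour of the taller;
- spikes in two channels are matched **greedily, one-to-one,
  nearest-day-first** within `window_days` (default 1 — same-day or
  next-day co-movement).

All three parameters are surfaced in `pipeline_config()`. The match count
is monotone in `window_days` and bounded by the smaller spike list, both
property-tested.

## The synthetic world

The generator's defaults state a world at the scale of the motivating
case study, fixed once: ~38,000 accounts in mixture
0.70/0.15/0.10/0.05 (individual/organizational/media/policy); log-normal
follower counts with median 200 (`sdlog` 1.4) as the standard heavy-tailed
stand-in; 90 days from 2014-01-01; Poisson posting at 90 posts/day off-spike
so the window totals ≈18,600 posts (case study: 16,071 regular tweets +
2,783 replies); 15% replies (2,783/18,854); keyword prevalence 0.85 (below
1 so the keyword filter has something to do); per-type retweet
propensities 0.6/0.25/0.2/0.15 expected retweets per 100 author followers,
which yields ≈40,000 retweets (case study: 40,193) and makes individuals
the strongest attractors; 13 shared spike days (every 7th day from day 5)
at tenfold intensity; a secondary newspaper-like channel at 5.8
mentions/day (518/90). All randomness flows from the single seed
(accounts, stream and trends draw from `seed`, `seed + 1`, `seed + 2`), and
equal configurations yield byte-identical output.

What the generator does **not** emulate: a follower graph (retweeters are
sampled uniformly from the pool — sufficient because no computed metric
uses graph topology beyond the retweet event itself), realistic text,
follower-count drift, diurnal rhythm, or coordinated/bot behaviour. A
green end-to-end test therefore establishes that the pipeline arithmetic
recovers planted structure, not that real streams satisfy the generator's
independence assumptions.

## Numerical and degenerate-input choices

- Counts are validated as non-negative integers; records violating an
  invariant are rejected with row numbers, never coerced.
- The contributor amplification identity is checked on read to within
  1e-9; files keep full double precision.
- Undefined statistics (zero impressions, zero grand total, zero
  variance, empty interaction matrix) raise errors; empty *inputs* to
  filters return empty outputs with a warning, since an empty stream is a
  legitimate (if degenerate) world.
- Timestamps are ISO-8601 strings compared at day granularity for trend
  work.

## Known limitations

The pipeline inherits the case study's design limits: literal keyword
matching misses paraphrase; a 90-day window cannot separate direction of
influence between channels (no lag or causality estimation is attempted,
deliberately); classification quality is bounded by the coding sheets
supplied; and the synthetic world's independence assumptions make it a
test harness, not a behavioural model of any real platform.
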