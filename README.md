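# isomip

Joint transcript identification and quantification from multi-sample
RNA-Seq by mixed-integer optimization.

## What problem this solves

Reconstructing the set of expressed RNA isoforms of a gene from
short-read RNA-Seq is under-determined: the splicing graph built from
spliced alignments usually encodes many more source-to-sink paths than
transcripts are expressed, and segment coverage from a single sample
often cannot single out the true set.  `isomip` is for analysts who
want transcript calls that (a) are selected and quantified *jointly*,
so coverage levels — not just structure — discriminate between
candidate sets, (b) pool several samples without merging their reads,
which is exactly what preserves the discriminating information, and
(c) come with a likelihood-ratio confidence value per transcript.

## The model

Over a splicing graph with segments `s`, intron edges `e` and samples
`r`, the package selects a set `T` of valid graph paths (binary rows
`u_t`) and nonnegative normalized abundances `W` minimizing

    sum_r [ sum_s L(V_obs[r,s], c * sum_t u_ts W_tr)
          + w_intron * sum_e L(I_obs[r,e], c * sum_t u_te W_tr)
          + w_pair * (read-pair counts no selected transcript explains) ]
          + w_sparsity * sum_{t in T} d_t

where `L(v, mu)` is the negative log-likelihood of count `v` under the
better of a negative-binomial signal (variance `mu + alpha*mu^2`) and a
background Poisson with mean `lambda` (so spurious coverage can be
"explained as noise" at bounded cost), `c` is the maximal observed
count, and `d_t` discounts annotated transcripts relative to novel
ones.  The integer search runs as best-first branch-and-bound over
path-selection indicators with convex piecewise-quadratic relaxations,
certifying global optimality on desk-scale loci; an iterative
one-transcript-at-a-time mode approximates larger ones.  Likelihood-
ratio tests score per-transcript confidence (chi-square, `df = R`) and
two-sample differential transcript expression (`df` = transcripts
tested).  A multi-mapper optimization loop reassigns ambiguous reads to
the loss-minimizing location, alternating with re-quantification.

## Worked example

Plant two isoforms of a three-exon gene (the second exon is a cassette)
at different abundances in two samples, simulate reads, and reconstruct:

```r
library(isomip)
set.seed(1)
chains <- list(
  inclusion = data.frame(start = c(0, 200, 400), end = c(100, 300, 500)),
  skip      = data.frame(start = c(0, 400),      end = c(100, 500)))
fx <- make_fixture(chains, abundances = cbind(c(0.7, 0.3), c(0.2, 0.8)),
                   dir = tempfile(), depth = 300, seed = 1)
gals  <- lapply(fx$sam, read_alignments)
graph <- build_segment_graph(gals, read_gtf(fx$gtf),
                             region = list(chrom = "chr1", start = 0, end = 600))
obs   <- count_observations(graph, gals)
model <- loss_model(kind = "nb", dispersion = 0.1, lambda_bg = 0.1)
fit   <- solve_joint(graph, obs, model,
                     hyper_params(w_sparsity = 2, w_pair = 0.1))
fit
#> solve_result: 2 transcripts, objective 46.6458 (optimal, 13 nodes)
#>   fit 42.6458 + pair 0 + sparsity 4
fit$tset$U                       # selected paths (segments: exon1, cassette, exon3)
#>      [,1] [,2] [,3]
#> [1,]    1    0    1
#> [2,]    1    1    1
round(fit$W * fit$c, 1)          # abundances, transcripts x samples
#>      [,1] [,2]
#> [1,] 25.9 76.4
#> [2,] 44.8 11.2
```

The solver certifies the two-transcript optimum after 13
branch-and-bound nodes.  Row 1 is the skip isoform, row 2 the
inclusion isoform; the recovered per-sample abundances (in average
reads per base) mirror the planted 0.7/0.3 vs 0.2/0.8 mix at depth
300.  Both transcripts are indispensable for the coverage they
explain, and the isoform switch between the samples is highly
significant:

```r
transcript_confidence(fit$tset, obs, model)[, c("statistic", "df", "p_value")]
#>   statistic df p_value
#> 1  1260.786  2       0
#> 2  1660.975  2       0
dt <- diff_expression_test(fit$tset, obs, model)
#> diff expression: stat 27.1, df 2, p = 1.29e-06
```

The identifiability simulation behind the multi-sample design argument
is a first-class module:

```r
set.seed(1)
100 * success_rates(n_cassettes = 3, set_size = 3, n_samples = 4,
                    n_trials = 50)
#>     unique_fraction optimal_strategy_fraction
#>                  86                        93
random_guess_probability(8, 3)   # guessing 3 of 8, in percent
#> [1] 1.785714
```

With three of eight possible transcripts expressed, one sample leaves
the set ambiguous in most trials, while four samples identify it
uniquely in the high eighties of percent — picking at random would
succeed 1.8% of the time.

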