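# dgrnn — knowledge-graph-guided recurrent clinical risk prediction

`dgrnn` is an R package for predicting a binary clinical outcome (the
motivating task is heart-failure onset) from longitudinal electronic
health record (EHR) event sequences, for biostatisticians and clinical
ML researchers who need the prediction to be **interpretable at the
level of individual medical events**.

## The model

For a patient's time-ordered coded events $v_1,\dots,v_T$, an LSTM runs
twice per event: first on the event embedding concatenated with a
sinusoidal encoding of its day offset, $[e_t; p_t] \to h_{2t-1},
C_{2t-1}$; then on the result of a soft attention step over the event's
edges in a medical knowledge graph,

$$s_{t,m} = u_a^\top\tanh\big(W_a[C_{2t-1}; e_{v_t}; e_{r_{t,m}};
e_{t,m}] + b_a\big),\quad
g_t = \textstyle\sum_m \mathrm{softmax}(s_t)_m\, e_{t,m},$$

giving $[g_t; p_t] \to h_{2t}$. A **global max pooling** over all $2T$
output vectors feeds a linear head, $z = W_o^\top o_g + b_o$,
$y = \sigma(z)$. Because the pooled maximum has an argmax structure,
the logit decomposes *exactly* into per-event credits — each pooled
dimension's term $W_o[j]\,o_g[j]$ is credited to the output row that
won it — separating every event's own contribution from the
contribution of its knowledge-graph neighbourhood. Ablation variants
`nk` (no knowledge step) and `np` (no pooling; last hidden state) are
built in.

Around the model the package provides: EHR table and triple-list I/O,
rare-code filtering and age/sex-matched case-control cohort assembly
with hold-off windows, TransE embedding pretraining, drug-aware
resampled Adam training, AUROC/sensitivity/specificity evaluation with
bootstrap model comparison, risk trajectories over visit prefixes,
what-if editing (remove codes / add a drug), t-SNE projection of pooled
patient vectors, a synthetic EHR + knowledge-graph simulator with a
known risk mechanism, and a CLI (`inst/cli/dgrnn`) with JSON exports
for visualization front ends.

## Worked example

Simulate a cohort whose outcome is driven by known risk codes and their
*causes* edges to the disease entity, train, and attribute:

```r
library(dgrnn)

cfg    <- sim_config(n_patients = 800, seed = 42)
sim    <- simulate_kg(cfg)
cohort <- simulate_cohort(sim, cfg)$cohort
cohort
#> <ehr_cohort: 233 cases + 567 controls, 59937 events (299 unique), hold-off 0 days>
#>   mean record length 74.92, mean events/visit 2.21

model <- dgrnn_init(dgrnn_config(embed_dim = 32, time_dim = 16,
                                 hidden_dim = 32, seed = 1),
                    cohort$vocabulary, sim$kg)
fit <- dgrnn_train(model, cohort, sim$kg,
                   train_config(batch_size = 64, epochs = 15,
                                learning_rate = 1e-3, seed = 1))
fit$val_metrics
#> <metrics_report: n=160, AUROC 0.9083, sens 0.3830, spec 1.0000 @ 0.50>
```

The validation AUROC of 0.91 sits just under the generating
mechanism's own ceiling of ~0.96 (the labels are Bernoulli draws, so
even the true logit cannot reach 1). Attribution decomposes one
high-risk patient's logit:

```r
case <- cohort$patients[[which.max(sapply(cohort$patients, function(p)
          sum(p$events$code %in% sim$risk_codes)))]]
rep <- dgrnn_attribute(fit$model, case, sim$kg)
head(rep$events[order(-rep$events$total_contribution), ], 5)
#>    event code   time total_contribution kg_contribution
#> 15    15  R14  307.8          0.1665416       0.1665416
#> 38    38  R12 1060.9          0.1472777       0.1472777
#> 30    30  R18  608.8          0.1410283       0.1410283
#> 9      9  R05  247.0          0.1263034       0.1263034
#> 74    74  R17 1393.9          0.1248899       0.1248899
```

The five largest contributions all belong to true risk codes (`R*`),
and most of their credit flows through the knowledge step — the
attention over their *causes* edges. The credits reconstruct the logit
exactly (`0.6772 = -0.0230 + 0.7001`), and a counterfactual edit shows
their causal weight in the model:

```r
wr <- whatif_remove(fit$model, case, sim$kg,
                    intersect(case$events$code, sim$risk_codes))
tail(wr$original$probability, 1)   # 0.6631
tail(wr$edited$probability, 1)     # 0.1628
```

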