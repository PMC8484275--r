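# edtriage

Hospital-admission prediction for urgent (level-3) emergency-department
patients, from ten variables available at the triage desk.

## What this is

Level-3 ("urgent") patients dominate ED volume and are the hardest to
stream: some will need admission, most will not, and the triage scale
itself cannot tell them apart. `edtriage` implements a compact,
reproducible prediction pipeline for this stratum:

* **Inputs** (canonical order): age, sex, temperature, heart rate,
  respiratory rate, systolic BP, diastolic BP, mean arterial pressure, a
  0–12 medical-history score, and a *chief-complaint risk value*
  $$v(\mathrm{cf}) = \frac{n_{h,r}+n_{h,d}}{n_t} +
  \frac{n_{h,d}}{n_{h,r}+n_{h,d}},$$
  the training-set admission fraction of the complaint code plus the
  death fraction among its admitted patients (0 for unseen codes and for
  codes with no admissions).
* **Model**: a three-layer feedforward network (output dimensions 100, 12,
  1) with batch normalization between layers and a sigmoid output —
  exactly $100d + 1549$ trainable parameters for $d$ inputs, 2549 for the
  full model. Trained with Adam on binary cross-entropy, early stopping on
  a training-internal monitor slice, fully seed-deterministic; the
  training loop is compiled (RcppArmadillo).
* **Evaluation**: ROC over all realized thresholds, tie-corrected
  Mann–Whitney AUC with DeLong 95% CI, Youden-index operating point,
  sensitivity/specificity/PPV/NPV with Wilson CIs, and per
  chief-complaint-category subgroup ROC/AUC.
* **Experiments**: training-fraction learning curve (100/75/50/25/12.5%,
  nested subsamples, encoder refit per condition) and variable ablation
  (10 / 9-no-complaint / 6-core / 5-core-no-complaint).
* **Synthetic cohorts**: a class-conditional generator pinned to the
  published cohort marginals (15.76% admission; per-disposition vital,
  age, history and category compositions) with a closed-form Bayes-optimal
  score (`true_admission_logit()`), so every pipeline stage is testable
  against a known upper bound without access to hospital data.

## Worked example

```r
library(edtriage)

cfg    <- default_cohort_config(n_visits = 12000, seed = 7)
visits <- generate_cohort(cfg)
split  <- split_train_validation(visits, 0.8, seed = 1)
table  <- fit_cc_risk_table(split$train)
x_tr   <- encode_features(split$train, table)
x_va   <- encode_features(split$validation, table)
model  <- train_admission_model(x_tr, admission_labels(split$train),
                                training_config(max_epochs = 20, seed = 1))
scores <- predict_admission_probability(model, x_va)
evaluate_predictions(scores, admission_labels(split$validation))
```

```
Validation evaluation (n = 2400 )
AUC 0.7475 (95% CI 0.7195-0.7754, delong; 386 pos / 2014 neg)
Youden cutoff 0.1418 (J = 0.3853)
Operating point at cutoff 0.1418
  counts: TP 239, FP 471, TN 1543, FN 147
  sensitivity  0.6192 (95% CI 0.5698-0.6662)
  specificity  0.7661 (95% CI 0.7472-0.7841)
  ppv          0.3366 (95% CI 0.3028-0.3722)
  npv          0.9130 (95% CI 0.8986-0.9255)
```

Reading this: the AUC is the probability a randomly chosen admitted
patient outscores a randomly chosen discharged one (with its DeLong 95%
interval); the Youden cutoff is the probability threshold maximizing
sensitivity + specificity − 1; the four metrics below it describe the
classifier operated at that cutoff, each with a Wilson 95% interval. At
this small demonstration size the intervals are wide; the shipped checks
run the same pipeline at 2×10⁵ visits, where the full ten-variable model
sits near AUC 0.81 against the generator's Bayes bound of ≈ 0.82, and
reproduce the two qualitative findings built into the design: training on
12.5% of the data costs real discrimination, and dropping the
chief-complaint risk value costs more than dropping four vital signs.

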