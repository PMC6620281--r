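# Published summary inputs

Small plain-text tables of *published summary statistics* (raw
confusion-table counts of a fibrosis-staging ROC analysis, per-group
coefficients of variation, and mean histology component scores) used as
inputs by `scripts/acceptance.R` and the acceptance tests. These are
printed aggregate numbers, not patient-level data; no clinical images or
per-subject scores are shipped.

- `published_confusion_counts.csv` — raw tp/fp/tn/fn counts at the reported
  LSN threshold for the three fibrosis-stratum comparisons.
- `published_group_cv.csv` — per-group CV (%) of LSN measurements.
- `published_nas_components.csv` — group-mean steatosis, lobular
  inflammation and ballooning scores (NAS components).
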