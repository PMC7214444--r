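# Elderly type 2 diabetes: sitagliptin vs. glimepiride.
# Representative, operationalizable subset of the published eligibility
# criteria; the indication concept set exercises descendant inclusion with
# selective exclusion (type 1 diabetes removed from the diabetes closure).
trial_id: sitagliptin_glimepiride
indication:
  concept_set:
    include:
      - id: C_DM
        descendants: true
    exclude:
      - id: C_T1DM
        descendants: true
eligibility:
  - kind: age_range
    min: 65
  - kind: measurement_threshold
    concept_set:
      include:
        - id: M_HBA1C
          descendants: false
    window:
      days_before: 365
      days_after: 0
    comparator: "<="
    bound: 9.0
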