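# RENAAL: losartan vs. placebo in type 2 diabetic nephropathy.
# Age band and serum-creatinine corridor are the trial's hard screening
# criteria; the survival criterion is a soft (judgment-based) criterion kept
# only as a documented unoperationalizable marker.
trial_id: renaal
indication:
  concept_set:
    include:
      - id: C_DIABETIC_NEPHROPATHY
        descendants: true
eligibility:
  - kind: age_range
    min: 31
    max: 70
  - kind: measurement_threshold
    concept_set:
      include:
        - id: M_CREATININE
          descendants: false
    window:
      days_before: 365
      days_after: 0
    comparator: between
    bounds: [1.3, 3.0]
  - kind: unoperationalizable
    description: Expected survival of at least two years
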