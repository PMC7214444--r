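# PROVE-IT: atorvastatin vs. pravastatin after acute coronary syndrome.
# Indication resolves through the ACS hierarchy (unstable angina, NSTEMI,
# STEMI). Total cholesterol ceiling is the trial's screening lipid criterion.
trial_id: prove_it
indication:
  concept_set:
    include:
      - id: C_ACS
        descendants: true
eligibility:
  - kind: age_range
    min: 18
  - kind: measurement_threshold
    concept_set:
      include:
        - id: M_TC
          descendants: false
    window:
      days_before: 365
      days_after: 0
    comparator: "<="
    bound: 240.0
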