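# ACCOMPLISH: benazepril-amlodipine vs. benazepril-HCTZ in high-risk
# systolic hypertension. Indication resolves through the hypertension
# hierarchy; age floor and prior antihypertensive exposure are hard criteria.
trial_id: accomplish
indication:
  concept_set:
    include:
      - id: C_HTN
        descendants: true
eligibility:
  - kind: age_range
    min: 55
  - kind: has_event
    concept_set:
      include:
        - id: D_AHT
          descendants: true
    window:
      days_before: 3650
      days_after: 0
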