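# Default extraction lexicon: entity labels, surface patterns, abbreviation
# and misspelling tables. Patterns are PCRE, applied to preprocessed
# (lowercased, symbol-stripped, table-normalized) section text.
#
# Entry forms:
#   - named capture groups matching case-facts field names -> one mention per
#     group (pattern: '...(?<gcs_total>\d+)...')
#   - field + value: fixed-value mention when the pattern matches
#   - field + normalizer: 'value' (and optionally 'unit') groups are
#     normalized (number, volume_ml, length_mm)
#   - field + map: the 'value' group is mapped through an enumeration table
# Logical-field entries are negated (value -> false) when a negation cue
# appears earlier in the same clause, unless negatable: false.

abbreviations:
  pt: patient
  "c/o": complains of
  bp: blood pressure
  hr: heart rate
  spo2: oxygen saturation
  sat: oxygen saturation
  hx: history
  h/o: history of

misspellings:
  haedache: headache
  hedache: headache
  headach: headache
  nausia: nausea
  nasuea: nausea
  vomitting: vomiting
  vommiting: vomiting
  anisocria: anisocoria
  annisocoria: anisocoria
  heamatoma: hematoma
  hematome: hematoma
  haematoma: hematoma
  cerebelum: cerebellum
  cerrebellum: cerebellum
  ganlia: ganglia
  ganglion: ganglia
  thalmus: thalamus
  deterioating: deteriorating
  deterioriating: deteriorating
  reactiv: reactive
  puplis: pupils
  glasgow coma scale: gcs
  glasgow coma score: gcs

entries:
  - label: gcs_total
    pattern: 'gcs (?:score )?(?:is |of )?(?<gcs_total>\d{1,2})\b'
  - label: gcs_components
    pattern: '\be(?<gcs_eye>[1-4])v(?<gcs_verbal>[1-5])m(?<gcs_motor>[1-6])\b'
  - label: heart_rate
    pattern: 'heart rate (?:is |of )?(?<heart_rate>\d{2,3})\b'
  - label: blood_pressure
    pattern: 'blood pressure (?:is |of )?(?<systolic_bp>\d{2,3})\s*/\s*(?<diastolic_bp>\d{2,3})\b'
  - label: spo2
    pattern: 'oxygen saturation (?:is |of )?(?<spo2>\d{1,3})\b'
  - label: consciousness
    field: consciousness_grade
    pattern: '\b(?<value>alert|drowsy|obtunded|stuporous|comatose)\b'
    map:
      alert: alert
      drowsy: drowsy
      obtunded: drowsy
      stuporous: stupor
      comatose: coma
  - label: pupils_equal
    field: pupil_state
    value: equal_reactive
    pattern: 'pupils (?:are )?equal(?:, round,?)?(?: and)? reactive(?: to light)?'
  - label: pupils_anisocoria
    field: pupil_state
    value: anisocoria
    pattern: '\banisocoria\b|pupils (?:are )?unequal'
  - label: pupils_fixed_dilated
    field: pupil_state
    value: bilateral_fixed_dilated
    pattern: 'pupils (?:are )?fixed and dilated(?: bilaterally)?|bilaterally fixed and dilated pupils'
  - label: pathological_reflex
    field: pathological_reflex
    value: 'true'
    pattern: 'pathological reflex(?:es)?|babinski sign'
  - label: symptom_headache
    field: headache
    value: 'true'
    pattern: '\bheadache\b'
  - label: symptom_nausea
    field: nausea
    value: 'true'
    pattern: '\bnausea\b'
  - label: symptom_vomiting
    field: vomiting
    value: 'true'
    pattern: '\bvomiting\b'
  - label: location_basal_ganglia
    field: bleed_location
    value: basal_ganglia
    pattern: 'basal ganglia'
  - label: location_thalamus
    field: bleed_location
    value: thalamus
    pattern: '\bthalam(?:us|ic)\b'
  - label: location_lobar
    field: bleed_location
    value: lobar
    pattern: '\b(?:frontal|temporal|parietal|occipital) lobe\b|\blobar\b'
  - label: location_cerebellum
    field: bleed_location
    value: cerebellum
    pattern: '\bcerebell(?:um|ar)\b'
  - label: location_brainstem
    field: bleed_location
    value: brainstem
    pattern: '\b(?:brainstem|brain stem|pons|pontine)\b'
  - label: location_ivh
    field: bleed_location
    value: intraventricular_primary
    pattern: 'primary intraventricular hemorrhage'
  - label: laterality_left
    field: laterality
    value: left
    pattern: '\bleft\b'
  - label: laterality_right
    field: laterality
    value: right
    pattern: '\bright\b'
  - label: laterality_bilateral
    field: laterality
    value: bilateral
    pattern: '\bbilateral\b'
  - label: laterality_midline
    field: laterality
    value: midline
    pattern: '\bmidline\b(?! (?:shift|structure))'
  - label: hematoma_volume
    field: hematoma_volume_ml
    normalizer: volume_ml
    pattern: '\b(?<value>\d+(?:\.\d+)?)\s*(?<unit>ml|cc)\b'
  - label: midline_shift
    field: midline_shift_mm
    normalizer: length_mm
    pattern: '(?:midline shift|shift of (?:the )?midline(?: structures?)?) (?:of |by |is )?(?<value>\d+(?:\.\d+)?)\s*(?<unit>mm|cm)\b'
  - label: midline_shift_none
    field: midline_shift_mm
    value: '0'
    pattern: 'no (?:evidence of )?midline shift'
    negatable: false
  - label: ventricle_cast
    field: ventricle_cast
    value: 'true'
    pattern: 'ventricular system is cast with blood|casting of the ventric(?:les|ular system)|ventricles? (?:are|is) cast'
  - label: ventricle_shape_abnormal
    field: ventricle_shape_abnormal
    value: 'true'
    pattern: 'ventricles (?:are|appear) (?:compressed|deformed|enlarged|effaced)'
  - label: ventricle_shape_normal
    field: ventricle_shape_abnormal
    value: 'false'
    pattern: 'ventricles (?:are|appear) normal in (?:shape|size and shape)'
    negatable: false
  - label: trend_deteriorating
    field: condition_trend
    value: deteriorating
    pattern: '(?:condition|patient) (?:is|was|has been|remains) (?:deteriorating|worsening|declining)|progressive deterioration'
  - label: trend_stable
    field: condition_trend
    value: stable
    pattern: '(?:condition|patient) (?:is|was|has been|remains) (?:relatively )?stable'
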