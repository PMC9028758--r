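# Default ICH treatment logic table: a guideline-derived stand-in encoding
# widely published surgical indications. Mandate rules force Plan I
# (emergency surgery) outright and carry weight 0; weighted rules accumulate
# into the normalized score thresholded at cut_high / cut_low.
#
# Comparators: eq, ne, lt, le, gt, ge, in, unknown, known. A rule's
# conditions are a conjunction; an unknown (null) field never satisfies a
# comparator, so missing data cannot mandate surgery.

cut_high: 0.5
cut_low: 0.15

rules:
  # --- mandatory surgical indications -----------------------------------
  - rule_id: cerebellar_hematoma_ge10ml
    mandate: true
    weight: 0
    when:
      - {field: bleed_location, op: eq, value: cerebellum}
      - {field: hematoma_volume_ml, op: ge, value: 10}
  - rule_id: cerebellar_with_ventricular_cast
    mandate: true
    weight: 0
    when:
      - {field: bleed_location, op: eq, value: cerebellum}
      - {field: ventricle_cast, op: eq, value: true}
  - rule_id: cerebellar_brainstem_compression
    mandate: true
    weight: 0
    when:
      - {field: bleed_location, op: eq, value: cerebellum}
      - {field: consciousness_grade, op: in, value: [stupor, coma]}
  - rule_id: supratentorial_mass_low_gcs
    mandate: true
    weight: 0
    when:
      - {field: bleed_location, op: in, value: [basal_ganglia, thalamus, lobar]}
      - {field: hematoma_volume_ml, op: ge, value: 30}
      - {field: gcs_total, op: le, value: 8}
  - rule_id: bilateral_fixed_dilated_pupils
    mandate: true
    weight: 0
    when:
      - {field: pupil_state, op: eq, value: bilateral_fixed_dilated}
  - rule_id: anisocoria_with_coma
    mandate: true
    weight: 0
    when:
      - {field: pupil_state, op: eq, value: anisocoria}
      - {field: consciousness_grade, op: eq, value: coma}

  # --- graded severity (weighted) ---------------------------------------
  - rule_id: supratentorial_volume_ge30
    weight: 3
    when:
      - {field: bleed_location, op: in, value: [basal_ganglia, thalamus, lobar]}
      - {field: hematoma_volume_ml, op: ge, value: 30}
  - rule_id: gcs_le8
    weight: 3
    when:
      - {field: gcs_total, op: le, value: 8}
  - rule_id: midline_shift_ge5mm
    weight: 2
    when:
      - {field: midline_shift_mm, op: ge, value: 5}
  - rule_id: ventricular_cast
    weight: 2
    when:
      - {field: ventricle_cast, op: eq, value: true}
  - rule_id: deteriorating_course
    weight: 2
    when:
      - {field: condition_trend, op: eq, value: deteriorating}
  - rule_id: anisocoria
    weight: 2
    when:
      - {field: pupil_state, op: eq, value: anisocoria}
  - rule_id: volume_ge10
    weight: 1
    when:
      - {field: hematoma_volume_ml, op: ge, value: 10}
  - rule_id: gcs_le12
    weight: 1
    when:
      - {field: gcs_total, op: le, value: 12}
  - rule_id: pathological_reflex
    weight: 1
    when:
      - {field: pathological_reflex, op: eq, value: true}
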