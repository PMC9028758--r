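# Narrative sentence templates for the synthetic eEMR renderer. One sentence
# per clinical fact; with all noise rates 0 the rendering is canonical and
# fully invertible by the default lexicon.

chief_complaint:
  positive: "the patient complains of {symptoms}"
  negative: "denies {symptoms}"
  none: "the patient presents for urgent neurological evaluation"

history:
  onset: "sudden onset of symptoms at home earlier today."
  background: "history of hypertension on irregular medication."
  trend: "the condition is {trend}."

physical_exam:
  gcs: "gcs {total} (e{eye}v{verbal}m{motor})."
  heart_rate: "heart rate {hr} bpm."
  blood_pressure: "blood pressure {sbp}/{dbp} mmhg."
  spo2: "oxygen saturation {spo2}%."
  consciousness: "the patient is {grade}."
  pupils:
    equal_reactive: "pupils are equal and reactive to light."
    anisocoria: "anisocoria is noted."
    bilateral_fixed_dilated: "pupils are fixed and dilated bilaterally."
  reflex_present: "pathological reflex is present."
  reflex_absent: "no pathological reflex is elicited."

ct_report:
  location: "hemorrhage centered in the {laterality} {location}."
  location_midline: "hemorrhage centered in the {location}, midline."
  location_ivh: "primary intraventricular hemorrhage, midline."
  volume: "the hematoma volume is approximately {volume} {unit}."
  shift: "midline shift of {shift} {unit}."
  no_shift: "no midline shift."
  cast_present: "the ventricular system is cast with blood."
  cast_absent: "no casting of the ventricular system."
  shape_abnormal: "the ventricles are compressed."
  shape_normal: "the ventricles are normal in shape."

consciousness_words:
  alert: alert
  drowsy: drowsy
  stupor: stuporous
  coma: comatose

trend_words:
  stable: stable
  deteriorating: deteriorating

location_words:
  basal_ganglia: [basal ganglia]
  thalamus: [thalamus]
  lobar: [frontal lobe, temporal lobe, parietal lobe, occipital lobe]
  cerebellum: [cerebellum]
  brainstem: [brainstem]

noise_symbols: ["***", "##", "~~", "^^", "==="]
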