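# Band/weight definitions for the two component early warning scores.
#
# Numeric bands are lower-inclusive, upper-exclusive half-open intervals
# [lower, upper) on the measured scale; each entry gives the exclusive upper
# bound of one band (.inf closes the line), so every real value maps to
# exactly one weight. Published inclusive integer cut-offs were converted to
# this convention once, at transcription time; values landing exactly on a
# printed cut-off score in the higher-risk band.
#
# The NEWS half is the Royal College of Physicians NEWS (2012) weighting.
# The LDT-EWS half is a reconstruction: decision-tree-derived cut-offs of
# the original score are not reproduced here, so bands use standard adult
# reference-range limits, with sex-specific haemoglobin and creatinine
# cut-offs, and per-analyte maximum weights chosen so the aggregate maximum
# is the score's declared 15. Replace this block with an exact transcription
# if you hold the original cut-offs; all scoring code is driven by this file.

news:
  max: 20
  components:
    respiratory_rate:
      unit: breaths/min
      bands:
        - {upper: 9, weight: 3}
        - {upper: 12, weight: 1}
        - {upper: 21, weight: 0}
        - {upper: 25, weight: 2}
        - {upper: .inf, weight: 3}
    spo2:
      unit: "%"
      bands:
        - {upper: 92, weight: 3}
        - {upper: 94, weight: 2}
        - {upper: 96, weight: 1}
        - {upper: .inf, weight: 0}
    supplemental_oxygen:
      kind: binary
      weight_true: 2
      weight_false: 0
    temperature:
      unit: degC
      bands:
        - {upper: 35.1, weight: 3}
        - {upper: 36.1, weight: 1}
        - {upper: 38.1, weight: 0}
        - {upper: 39.1, weight: 1}
        - {upper: .inf, weight: 2}
    systolic_bp:
      unit: mmHg
      bands:
        - {upper: 91, weight: 3}
        - {upper: 101, weight: 2}
        - {upper: 111, weight: 1}
        - {upper: 220, weight: 0}
        - {upper: .inf, weight: 3}
    heart_rate:
      unit: beats/min
      bands:
        - {upper: 41, weight: 3}
        - {upper: 51, weight: 1}
        - {upper: 91, weight: 0}
        - {upper: 111, weight: 1}
        - {upper: 131, weight: 2}
        - {upper: .inf, weight: 3}
    consciousness:
      kind: categorical
      weights: {A: 0, V: 3, P: 3, U: 3}

ldtews:
  max: 15
  components:
    albumin:
      unit: g/L
      bands:
        - {upper: 18, weight: 3}
        - {upper: 25, weight: 2}
        - {upper: 33, weight: 1}
        - {upper: .inf, weight: 0}
    urea:
      unit: mmol/L
      bands:
        - {upper: 12, weight: 0}
        - {upper: 20, weight: 1}
        - {upper: 30, weight: 2}
        - {upper: .inf, weight: 3}
    sodium:
      unit: mmol/L
      bands:
        - {upper: 125, weight: 2}
        - {upper: 132, weight: 1}
        - {upper: 146, weight: 0}
        - {upper: 150, weight: 1}
        - {upper: .inf, weight: 2}
    potassium:
      unit: mmol/L
      bands:
        - {upper: 3.0, weight: 2}
        - {upper: 3.5, weight: 1}
        - {upper: 5.5, weight: 0}
        - {upper: 6.0, weight: 1}
        - {upper: .inf, weight: 2}
    wcc:
      unit: 10^9 cells/L
      bands:
        - {upper: 2, weight: 2}
        - {upper: 4, weight: 1}
        - {upper: 12, weight: 0}
        - {upper: 20, weight: 1}
        - {upper: .inf, weight: 2}
    haemoglobin:
      unit: g/L
      sex_specific: true
      male:
        bands:
          - {upper: 85, weight: 2}
          - {upper: 115, weight: 1}
          - {upper: .inf, weight: 0}
      female:
        bands:
          - {upper: 80, weight: 2}
          - {upper: 105, weight: 1}
          - {upper: .inf, weight: 0}
    creatinine:
      unit: umol/L
      sex_specific: true
      male:
        bands:
          - {upper: 170, weight: 0}
          - {upper: .inf, weight: 1}
      female:
        bands:
          - {upper: 150, weight: 0}
          - {upper: .inf, weight: 1}

# Glasgow Coma Scale -> AVPU conversion (inclusive integer ranges).
gcs_to_avpu:
  A: [15, 15]
  V: [13, 14]
  P: [9, 12]
  U: [3, 8]

# Physiological plausibility bounds enforced when vitals are read (inclusive).
plausibility:
  heart_rate: [10, 300]
  systolic_bp: [30, 300]
  respiratory_rate: [1, 80]
  temperature: [30, 43]
  spo2: [40, 100]
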