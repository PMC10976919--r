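# TNM 8th edition staging rules for lung cancer (T and N only).
# Kept as versioned configuration so a revised edition can be dropped in
# without code changes.
version: "tnm8-1.0"

# Size buckets for the primary tumor, long axis in millimeters.
# Boundaries are inclusive ("<= threshold"), so a 30 mm tumor is T1c.
# A missing max_mm means "anything larger".
t_size_thresholds_mm:
  - {max_mm: 10, stage: T1a}
  - {max_mm: 20, stage: T1b}
  - {max_mm: 30, stage: T1c}
  - {max_mm: 40, stage: T2a}
  - {max_mm: 50, stage: T2b}
  - {max_mm: 70, stage: T3}
  - {stage: T4}

# Feature-based overruling: the final T is the maximum of the size stage and
# the feature stage.  A T2 feature with a known size lifts the stage to at
# least T2a; without any size it yields the generic label T2.
feature_to_t:
  T2: T2
  T3: T3
  T4: T4
  satellite_same_lobe: T3
  separate_nodule_other_lobe: T4

# CT criterion for a pathologic lymph node: short axis >= 10 mm.
node_size_cutoff_mm: 10

# IASLC nodal stations 1-14 mapped to N stage by laterality relative to the
# primary tumor.  Station 1 (supraclavicular/scalene) is N3 on either side;
# station 7 (subcarinal) is N2 on either side.
station_to_n:
  ipsilateral:
    1: N3
    2: N2
    3: N2
    4: N2
    5: N2
    6: N2
    7: N2
    8: N2
    9: N2
    10: N1
    11: N1
    12: N1
    13: N1
    14: N1
  contralateral:
    1: N3
    2: N3
    3: N3
    4: N3
    5: N3
    6: N3
    7: N2
    8: N3
    9: N3
    10: N3
    11: N3
    12: N3
    13: N3
    14: N3
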