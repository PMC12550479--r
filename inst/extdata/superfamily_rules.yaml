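# Superfamily diagnostic rules, applied in ascending priority order; the
# first rule whose constraints all hold assigns the label. Editable without
# code changes.
#
# Recognised constraint keys:
#   micron_context: true        element must sit in (TA)n/(CA)n/(GT)n context
#   min_units, window           microsatellite run length / search window
#   tsd_exact: [..]             TSD must equal one of these strings
#   tsd_len_min, tsd_len_max    TSD length range (bp)
#   tir_prefix_regex            regex anchored anywhere in the TIR string
#   tir_len_min, tir_len_max    TIR length range (bp)
rules:
  - name: Micron
    priority: 1
    micron_context: true
    min_units: 5
    window: 20
  - name: CACTA
    priority: 2
    tsd_len_min: 2
    tsd_len_max: 3
    tir_prefix_regex: "^CACT[AG]"
  - name: Tc1/Mariner
    priority: 3
    tsd_exact: [TA]
  - name: PIF/Harbinger
    priority: 4
    tsd_exact: [TAA, TTA]
  - name: hAT
    priority: 5
    tsd_len_min: 8
    tsd_len_max: 8
    tir_len_min: 5
    tir_len_max: 27
  - name: Mutator
    priority: 6
    tsd_len_min: 8
    tsd_len_max: 10
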