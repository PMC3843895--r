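# NMDA-receptor kinetic scheme (no Mg2+ block).
#
# Five states: unbound (C0), singly (C1) and doubly (C2) bound closed states,
# a desensitised state (D) and an open state (O), both entered from C2.
# Rate constants follow the classical two-binding-site NMDAR gating model of
# Lester & Jahr with statistical factors of two on the first binding and the
# second unbinding step. Voltage-dependent Mg2+ block is deliberately absent:
# the model studies glutamate-driven gating only.
name: NMDAR (two-binding-site scheme, no Mg block)
states: [C0, C1, C2, D, O]
initial_state: C0
open_states: [O]
conductance_pS: 25.0
reversal_mV: 0.0
temperature:
  q10: 2.0
  reference_C: 25.0
  target_C: 33.0
transitions:
  - {from: C0, to: C1, rate: 1.00e7, unit: per_M_per_s}   # 2 x kon
  - {from: C1, to: C0, rate: 8.20e1, unit: per_s}          # koff
  - {from: C1, to: C2, rate: 5.00e6, unit: per_M_per_s}   # kon
  - {from: C2, to: C1, rate: 1.64e2, unit: per_s}          # 2 x koff
  - {from: C2, to: O,  rate: 4.65e1, unit: per_s}          # opening
  - {from: O,  to: C2, rate: 9.16e1, unit: per_s}          # closing
  - {from: C2, to: D,  rate: 8.40e0, unit: per_s}          # desensitisation
  - {from: D,  to: C2, rate: 1.80e0, unit: per_s}          # recovery
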