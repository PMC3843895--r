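# Multi-stage AMPA-receptor kinetic scheme for hippocampal synapses.
#
# Seven states: unbound (C0), singly (C1) and doubly (C2) glutamate-bound
# closed states, one open state (O) entered from C2, and a desensitised
# branch (C3 singly bound, C4/C5 doubly bound) connected to C1, C2 and O.
# Rate constants follow the classical patch-clamp model of fast hippocampal
# AMPAR gating (Jonas/Major/Sakmann-type scheme, room-temperature fits);
# binding steps carry units of 1/(M s) and are multiplied by the local
# glutamate concentration at run time. A uniform Q10 multiplier scales all
# rates from the reference temperature to near-physiological temperature.
name: AMPAR (multi-stage hippocampal scheme)
states: [C0, C1, C2, C3, C4, C5, O]
initial_state: C0
open_states: [O]
conductance_pS: 12.5
reversal_mV: 0.0
temperature:
  q10: 2.0
  reference_C: 25.0
  target_C: 33.0
transitions:
  - {from: C0, to: C1, rate: 4.59e6, unit: per_M_per_s}   # first binding
  - {from: C1, to: C0, rate: 4.26e3, unit: per_s}
  - {from: C1, to: C2, rate: 2.84e7, unit: per_M_per_s}   # second binding
  - {from: C2, to: C1, rate: 3.26e3, unit: per_s}
  - {from: C2, to: O,  rate: 4.24e3, unit: per_s}          # opening
  - {from: O,  to: C2, rate: 9.00e2, unit: per_s}          # closing
  - {from: C1, to: C3, rate: 2.89e3, unit: per_s}          # desensitisation
  - {from: C3, to: C1, rate: 3.92e1, unit: per_s}
  - {from: C2, to: C4, rate: 1.72e2, unit: per_s}
  - {from: C4, to: C2, rate: 7.27e-1, unit: per_s}
  - {from: C3, to: C4, rate: 1.27e6, unit: per_M_per_s}   # binding while desensitised
  - {from: C4, to: C3, rate: 4.57e1, unit: per_s}
  - {from: C4, to: C5, rate: 1.77e1, unit: per_s}
  - {from: C5, to: C4, rate: 4.00e0, unit: per_s}
  - {from: O,  to: C5, rate: 1.68e1, unit: per_s}
  - {from: C5, to: O,  rate: 1.904e2, unit: per_s}
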