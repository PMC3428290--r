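{
  "A": 0.6,
  "tau_ns": 4.96,
  "B": 0.4,
  "note": "Reference parameters for the single-exponential strand-opening benchmark A*exp(-t/tau)+B. tau_ns is the published strand-opening time constant of the miR369-3:mRNA duplex in the PAZ/KH-bound quadruple complex; the A and B amplitudes are repository choices for the synthetic trace."
}
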