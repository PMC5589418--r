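# Example tracemet experiment configuration.
tracer: glutamine
tracer_shift: 5
steady_state_tol: 0.05
t_test: student
comparisons:
  - high: serum_cystine
    low: serum
    metabolite: alpha-ketoglutarate
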