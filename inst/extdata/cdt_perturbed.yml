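# Neuronal model with the synergistic drug-combination perturbation:
# tenfold activation of tyrosination (Vm2) and of detyrosinated-microtubule
# depolymerization (km1) once the system has reached its steady state.
variant: neuronal
horizon: 300
step: 0.1
seed: 1
events:
  - time: 60
    mode: fold
    assignments:
      km1: 10
      Vm2: 10
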