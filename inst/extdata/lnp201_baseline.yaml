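# Reference (LNP201) configuration: experimental setup and rate constants
# in table units. First-order constants in 1/hr; k4/k6 in L/(nM hr),
# converted on load with the intracellular volume.
schema_version: 1
label: LNP201 baseline
extracellular_volume_L: 3.0e-4
intracellular_volume_L: 1.4e-12
cell_count: 10000
dose_nM: 10
initial_risc: 10000
initial_mrna: 100
k1: 0.005
k2: 5.0e-4
k3: 3
k4_L_nM_hr: 0.001
k5: 0.03
k6_L_nM_hr: 0.1
k7: 7.2
k8: 100
k9: 1
t_delay_hr: 0
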