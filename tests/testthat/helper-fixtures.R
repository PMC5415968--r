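# Shared objects for the suite: the default experimental setup and the
# four-vehicle reference panel.
base_spec <- experiment_spec()
FX <- vehicle_fixtures()
baseline <- FX$LNP201$parameters

# molecules-per-cell equivalent of 1 nM in the cytoplasm (unit-conversion
# oracle computed from Avogadro arithmetic, independently of the package)
nm1_cyto <- 1e-9 * 1.4e-12 * 6.02214076e23
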