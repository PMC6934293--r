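# Bare platinum coil, 5 mm x 2 cm (reduced test size); wire and secondary
# dimensions of the Axium-class coils, synthetic pre-shape parameters.
d1_mm: 0.0381
d2_mm: 0.2921
d3_mm: 5
length_cm: 2
E_wire_gpa: 230
G_wire_gpa: 82
rho_wire: 21.45
section_convention: ANNULUS_AROUND_D2
lambda: 0.75
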