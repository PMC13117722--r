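# Default build configuration: 30 nm DPPC liposome in a 40 nm box.
# Leaflet reference radii invert N = 4*pi*r^2/APL at the target leaflet
# populations (5128 outer / 3638 inner) for APL 0.46 nm^2.  Water counts
# are fixed by configuration (the solvation lattice is trimmed to them).
species: DPPC
outer_diameter: 30.0    # nm
apl: 0.46               # nm^2
box_edge: 40.0          # nm
r_out_ref: 13.701       # nm, phosphate sphere of the outer leaflet
r_in_ref: 11.540        # nm, phosphate sphere of the inner leaflet
n_water_in: 67522       # beads
n_water_out: 334358     # beads
min_separation: 0.40    # nm
lattice_spacing: 0.415  # nm
jitter: 0.01            # nm, per-axis uniform
seed: 20260101
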