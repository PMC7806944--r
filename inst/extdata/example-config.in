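# Example configuration for a synthetic end-to-end run
calc_type = dock
method = DD
dd_type = TI-GQ
temperature = 298.15
components = a l t e v w f b c r
blocks = 4
seed = 7

# protein anchors (reference-frame selectors)
P1 = :15@CA
P2 = :8@CA
P3 = :22@CA

# strike zone / anchor search
l1_x = 0
l1_y = 0
l1_range = 4
l1_z = 3
l1_zm = 9
min_adis = 2
max_adis = 6

# force constants
rec_distance_force = 10
rec_angle_force = 100
rec_discf_force = 1
rec_dihcf_force = 150
lig_distance_force = 5
lig_angle_force = 250
lig_discf_force = 5
lig_dihcf_force = 70

# windows
attach_rest = [ 0 0.5 1 2 4 8 16 24 32 40 48 56 64 72 80 100 ]
lig_resname = LIG
n_samples = 500
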