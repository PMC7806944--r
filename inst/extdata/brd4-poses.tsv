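pose_id	initial_rmsd	equilibrated_rmsd	minus_dg_bind	sigma
crystal	0.00	1.30	6.1	0.6
pose1	5.36	5.26	2.5	0.9
pose2	2.00	0.45	6.7	0.6
pose3	5.58	5.33	2.6	0.8
pose4	5.50	4.23	1.5	0.6
pose5	1.07	0.74	6.5	0.8
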