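# Six commercial multitiered-aviary houses: measured aisle widths (meters,
# left wall to right wall relative to the entrance door), house width,
# structure-row count, flock size, and regulatory usable / littered floor
# areas. structure_width_printed_m is the rounded field-report value kept as
# a cross-check; all computation derives the structure width from the house
# and aisle widths.
# NOTE house 2: the published aisle widths are typographically ambiguous in
# the source table (the four values cannot be recovered unambiguously, and
# no parse reproduces the reported per-transect bird tallies); the values
# below are the closest plausible reading and are excluded from golden
# checks.
house_id,house_width_m,n_structures,flock_size,usable_area_m2,floor_area_m2,structure_width_printed_m,aisle_widths
1,14.0,3,7500,1850,1000,2.33,1.75;1.75;1.75;1.75
2,12.0,3,7700,990,506,1.96,1.54;1.51;1.51;1.54
3,11.0,2,7840,915,432,3.83,1.11;1.11;1.11
4,10.0,1,7200,815,385,5.78,2.11;2.11
5,12.0,2,7500,1005,648,4.41,1.03;1.10;1.04
6,11.0,3,7500,910,450,1.74,1.40;1.49;1.49;1.40
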