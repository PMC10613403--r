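# CA distance templates for secondary structure assignment (Angstrom).
# These are the package defaults, spelled out so alternative constants can
# be loaded with loadDistanceTemplates().
helix.d13 = 5.45
helix.d14 = 5.18
helix.d15 = 6.37
helix.d24 = 5.45
helix.d25 = 5.18
helix.d35 = 5.45
strand.d13 = 6.1
strand.d14 = 10.4
strand.d15 = 13.0
strand.d24 = 6.1
strand.d25 = 10.4
strand.d35 = 6.1
delta.helix = 2.1
delta.strand = 1.42
turn.d15 = 8.0
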