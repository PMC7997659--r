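# Example channelgeom configuration.
#
# Two-state comparison (subcommand: compare).  Paths are relative to the
# working directory.  Every default used is echoed into the JSON report.

input_a: state_a.pdb          # reference state (e.g. antagonist-bound)
input_b: state_b.pdb          # comparison state (e.g. desensitized)
out_dir: comparison_out
seed: 1

# Chain -> tetramer position mapping.  Use "infer" to assign A/C to the
# pore-proximal pair geometrically (needs >= 1 A radial separation).
mapping:
  - {position: A, subunit_type: GluK5, chain: A}
  - {position: B, subunit_type: GluK2, chain: B}
  - {position: C, subunit_type: GluK5, chain: C}
  - {position: D, subunit_type: GluK2, chain: D}

# Domain residue intervals per subunit type (author numbering, closed).
# Omit to use the shipped GluK2/GluK5 M3 and analysis-range defaults;
# LBD and lobe (LBD_D1 / LBD_D2) boundaries are model-specific and must
# be supplied for COM, tilt and cleft-closure stages to run.  The LBD
# values below are placeholders: replace them with the modeled residue
# ranges of your own entry.
scheme:
  GluK2:
    M3: [631, 664]
    analysis_range: [631, 676]
    LBD: [400, 500]
  GluK5:
    M3: [615, 648]
    analysis_range: [615, 660]
    LBD: [384, 484]

# Pore profiling overrides (subcommand: pore; `input` instead of input_a/b)
# pore:
#   z_step: 0.5
#   max_probe: 10
#   closed_cutoff: 1.15
# cutoff: 2.5           # exploratory constriction cutoff
# z_range: [-25, 15]
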