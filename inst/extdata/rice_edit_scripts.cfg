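# Gene-model curation scripts for the six revised rice serpins, in the
# plain-text format read by read_edit_scripts().  Identical to the scripts
# built in code by build_rice_scripts(); the PSG intron-segment anchors
# WIHD/DHIW are synthetic stand-ins (boundary residues were never printed).
script QKG Os01g16200
op trim_n_terminal_count 25
expect 398

script LRS Os03g41419
op excise WLLL TSGK
op replace_c_terminal AAEVLGQ VNPLLAA
expect 396

script PLP Os11g11500
op trim_n_terminal_to MPTRPW
expect 394

script PSG Os11g11760
op excise WIHD DHIW
op remove_run A 5
expect 417

script PTY Os04g45110
op trim_n_terminal_count 117
expect 393

script PGY Os04g45120
op trim_n_terminal_count 126
expect 398
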