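{
  "name": "PR_scaffold_synthetic",
  "description": "Designed (synthetic) proteorhodopsin-architecture reference frame: 319 aa, seven hydrophobic transmembrane helices separated by hydrophilic loops. Carries the green-absorbing proteorhodopsin DTE-L motif at the canonical positions 97/101/105/108 (bacteriorhodopsin 85/89/93/96) in helix 3 and the retinal-binding lysine at position 298, centred in helix 7. It is NOT a database record; it stands in for the canonical eBAC31A08 frame so that position numbering and hydropathy-based screening are exactly reproducible.",
  "synthetic": true,
  "motif_positions_pr": [97, 101, 105, 108],
  "motif_positions_br": [85, 89, 93, 96],
  "retinal_lysine_pr": 298,
  "tm_segments": [
    [3, 33],
    [48, 78],
    [93, 133],
    [148, 178],
    [193, 223],
    [238, 268],
    [283, 313]
  ]
}
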