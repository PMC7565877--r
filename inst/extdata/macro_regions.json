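{
  "comment": "Bundled MR1-MR20 diffusion-pathway topology for a multi-subunit RNA polymerase. Residue selections are system-specific placeholders supplied by the user. Adjacency encodes only the relations stated in the main-text map: the MR13 external bridge to MR3 and MR12, the interconnected funnel MR1/2/3/4, the MR1/4/5/6/7/8 common junction, and the per-channel chains into the terminal regions.",
  "regions": [
    {"name": "MR1",  "class": "entry",        "channels": ["CH2"],  "terminal": false},
    {"name": "MR2",  "class": "entry",        "channels": ["CH2"],  "terminal": false},
    {"name": "MR3",  "class": "entry",        "channels": ["CH2"],  "terminal": false},
    {"name": "MR4",  "class": "entry",        "channels": ["CH2"],  "terminal": false},
    {"name": "MR5",  "class": "entry",        "channels": ["CH3A"], "terminal": false},
    {"name": "MR6",  "class": "entry",        "channels": ["CH3B"], "terminal": false},
    {"name": "MR7",  "class": "entry",        "channels": ["CH3B"], "terminal": false},
    {"name": "MR8",  "class": "entry",        "channels": ["CH3C"], "terminal": false},
    {"name": "MR9",  "class": "entry",        "channels": ["CH3C"], "terminal": false},
    {"name": "MR10", "class": "entry",        "channels": ["CH3D"], "terminal": false},
    {"name": "MR11", "class": "entry",        "channels": ["CH3D"], "terminal": false},
    {"name": "MR12", "class": "entry",        "channels": ["CH3D"], "terminal": false},
    {"name": "MR13", "class": "external",     "channels": [],       "terminal": false},
    {"name": "MR14", "class": "infiltration", "channels": ["CH2"],  "terminal": false},
    {"name": "MR15", "class": "infiltration", "channels": ["CH3A"], "terminal": false},
    {"name": "MR16", "class": "infiltration", "channels": ["CH3B"], "terminal": false},
    {"name": "MR17", "class": "infiltration", "channels": ["CH3C"], "terminal": false},
    {"name": "MR18", "class": "infiltration", "channels": ["CH3D"], "terminal": false},
    {"name": "MR19", "class": "infiltration", "channels": [],       "terminal": true},
    {"name": "MR20", "class": "infiltration", "channels": [],       "terminal": true}
  ],
  "adjacency": [
    ["MR13", "MR3"], ["MR13", "MR12"],
    ["MR1", "MR2"], ["MR1", "MR3"], ["MR1", "MR4"],
    ["MR2", "MR3"], ["MR2", "MR4"], ["MR3", "MR4"],
    ["MR1", "MR5"], ["MR1", "MR6"], ["MR1", "MR7"], ["MR1", "MR8"],
    ["MR4", "MR5"], ["MR4", "MR6"], ["MR4", "MR7"], ["MR4", "MR8"],
    ["MR5", "MR6"], ["MR5", "MR7"], ["MR5", "MR8"],
    ["MR6", "MR7"], ["MR6", "MR8"], ["MR7", "MR8"],
    ["MR1", "MR14"], ["MR2", "MR14"], ["MR3", "MR14"], ["MR4", "MR14"],
    ["MR14", "MR20"],
    ["MR5", "MR15"], ["MR15", "MR19"],
    ["MR6", "MR16"], ["MR7", "MR16"], ["MR16", "MR19"],
    ["MR8", "MR17"], ["MR9", "MR17"], ["MR17", "MR19"],
    ["MR10", "MR18"], ["MR11", "MR18"], ["MR12", "MR18"],
    ["MR10", "MR11"], ["MR11", "MR12"], ["MR18", "MR19"],
    ["MR19", "MR20"]
  ]
}
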