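# Configuration schema for the peripose pipeline stages.
# Every run_* function accepts a named R list or a YAML file with these
# fields; unknown fields are rejected before any computation starts.
# Defaults shown are applied when a field is omitted.

common: # accepted by run_contacts, run_depth, run_tilt
  topology:            {type: string,  required: true,  doc: PDB structure path}
  trajectory:          {type: strings, required: true,  doc: one or more DCD/PDB paths (replicas)}
  out_dir:             {type: string,  required: true,  doc: output directory}
  protein_selection:   {type: string,  default: "protein and heavy"}
  membrane_selection:  {type: string,  default: "membrane and heavy"}
  window_fraction:     {type: number,  default: 0.5,    doc: trailing analysis window, fraction of frames in (0, 1]}
  dt_ns:               {type: number,  default: 1,      doc: frame spacing in ns}
  rewrap_z:            {type: logical, default: false,  doc: recentre the membrane at z = 0 per frame}
  seed:                {type: number,  default: 1}

contacts:
  steepness:           {type: number,  default: 5,      doc: contact kernel steepness, 1/Angstrom}
  midpoint:            {type: number,  default: 4,      doc: half-contact distance, Angstrom}
  threshold:           {type: number,  default: 0.5,    doc: association threshold, contacts}
  persistence_ns:      {type: number,  default: 10,     doc: state persistence for dissociation detection, ns}

depth:
  bin_width:           {type: number,  default: 0.5,    doc: depth histogram bin width, Angstrom}
  min_breach_probability: {type: number, default: 0.05}
  phosphate_selection: {type: string,  default: "name P and membrane"}
  absolute:            {type: logical, default: false,  doc: histogram |depth| instead of signed depth}

tilt:
  residue_a:           {type: string,  required: true,  doc: "anchor residue, 'chain:resid'"}
  residue_b:           {type: string,  required: true}
  bin_width:           {type: number,  default: 2,      doc: tilt bin width, degrees}
  kT:                  {type: number,  default: 1,      doc: thermal energy unit for the pose free energy}

fep:
  out_dir:             {type: string,  required: true}
  mutations:           {type: list,    required: true,  doc: list of {label, bound, solution} work-file paths}
  estimator:           {type: string,  default: BAR,    doc: BAR or EXP}
  temperature:         {type: number,  default: 310,    doc: Kelvin}
  lambda:              {type: numbers, default: [0, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.98, 1]}
  ns_per_window:       {type: number,  default: 3}
  seed:                {type: number,  default: 1}

simulate:
  out_dir:             {type: string,  required: true}
  seed:                {type: number,  default: 1}
  scale:               {type: number,  default: 0.5,    doc: membrane recipe scale (1 = 100 lipids/leaflet)}
  n_res:               {type: number,  default: 12,     doc: residues in the rigid protein template}
  replicas:            {type: list,    default: [{}],   doc: per-replica overrides of binding_scenario() fields}
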