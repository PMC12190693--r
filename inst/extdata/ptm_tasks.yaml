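# Default PTM task registry: the 13 tasks with their UniProt feature
# annotation strings and candidate residues. Matching is exact after
# whitespace normalization; edit or replace this file to define custom tasks.
- task_name: "Phosphorylation (S)"
  candidate_residue: "S"
  annotation_keys:
    - "Phosphoserine"
    - "Diphosphoserine"
    - "O-(2-cholinephosphoryl)serine"
    - "(Microbial infection) Phosphoserine"
    - "O-(pantetheine4′phosphoryl)serine"
    - "(Microbial infection) O-(2-cholinephosphoryl) serine"
- task_name: "Phosphorylation (T)"
  candidate_residue: "T"
  annotation_keys:
    - "(Microbial infection) Phosphothreonine"
    - "Phosphothreonine"
- task_name: "Phosphorylation (Y)"
  candidate_residue: "Y"
  annotation_keys:
    - "Phosphotyrosine"
- task_name: "Ubiquitination (K)"
  candidate_residue: "K"
  annotation_keys:
    - "(Microbial infection) Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in ubiquitin)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in ubiquitin and interchain with MARCHF2)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in ubiquitin)"
- task_name: "N-Linked Glycosylation (N)"
  candidate_residue: "N"
  annotation_keys:
    - "N-linked (GlcNAc…) (paucimannose) asparagine"
    - "N-linked (GlcNAc…) (keratan sulfate) asparagine"
    - "N-linked (GlcNAc…) (complex) asparagine"
    - "N-linked (GlcNAc) asparagine"
    - "N-linked (Glc…) asparagine"
    - "N-linked (GlcNAc…) (hybrid) asparagine"
    - "N-linked (GalNAc…) asparagine"
    - "N-linked (GlcNAc…) (polylactosaminoglycan) asparagine"
    - "N-linked (GlcNAc…) asparagine"
    - "N-linked (Hex) asparagine"
    - "N-linked (HexNAc…) asparagine"
    - "N-linked (GlcNAc…) (high mannose) asparagine"
- task_name: "O-Linked Glycosylation (S)"
  candidate_residue: "S"
  annotation_keys:
    - "O-linked (Xyl…) (dermatan sulfate) serine"
    - "O-linked (Fuc…) serine"
    - "O-linked (Xyl…) (heparan sulfate) serine"
    - "O-linked (HexNAc…) serine"
    - "O-linked (Fuc) serine"
    - "O-linked (GalNAc…) serine"
    - "O-linked (Xyl…) serine"
    - "O-linked (Hex…) serine"
    - "O-linked (GlcA) serine"
    - "O-linked (GlcNAc) serine"
    - "O-linked (GalNAc) serine"
    - "O-linked (Man…) serine"
    - "O-linked (Xyl…) (glycosaminoglycan) serine"
    - "O-linked (Hex) serine"
    - "O-linked (GlcNAc…) serine"
    - "O-linked (Glc…) serine"
    - "O-linked (Xyl…) (chondroitin sulfate) serine"
    - "O-linked (Man) serine"
- task_name: "O-Linked Glycosylation (T)"
  candidate_residue: "T"
  annotation_keys:
    - "O-linked (GlcNAc…) threonine"
    - "O-linked (Xyl…) (keratan sulfate) threonine"
    - "O-linked (Hex) threonine"
    - "O-linked (GalNAc) threonine"
    - "O-linked (GalNAc…) threonine"
    - "O-linked (GlcNAc) threonine"
    - "(Microbial infection) O-linked (Glc) threonine"
    - "O-linked (Fuc) threonine"
    - "O-linked (HexNAc) threonine"
    - "O-linked (Man6P…) threonine"
    - "O-linked (Man…) threonine"
    - "O-linked (Fuc…) threonine"
    - "O-linked (HexNAc…) threonine"
    - "O-linked (Hex…) threonine"
    - "O-linked (Man) threonine"
- task_name: "Acetylation (K)"
  candidate_residue: "K"
  annotation_keys:
    - "N6-acetyllysine"
    - "N6-acetyl-N6-methyllysine"
    - "(Microbial infection) N6-acetyllysine"
- task_name: "Palmitoylation (C)"
  candidate_residue: "C"
  annotation_keys:
    - "N-palmitoyl cysteine"
    - "S-palmitoyl cysteine"
- task_name: "Methylation (R)"
  candidate_residue: "R"
  annotation_keys:
    - "Asymmetric dimethylarginine"
    - "N5-[4-(S-L-cysteinyl)-5-methyl-1H-imidazol-2-yl]-L-ornithine (Arg-Cys) (interchain with C-151 in KEAP1)"
    - "Symmetric dimethylarginine"
    - "Dimethylated arginine"
    - "Omega-N-methylated arginine"
    - "Omega-N-methylarginine"
- task_name: "Methylation (K)"
  candidate_residue: "K"
  annotation_keys:
    - "N6-acetyl-N6-methyllysine"
    - "N6-methyllysine"
    - "N6,N6,N6-trimethyllysine"
    - "N6-methylated lysine"
    - "N6,N6-dimethyllysine"
- task_name: "SUMOylation (K)"
  candidate_residue: "K"
  annotation_keys:
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO1, SUMO2 and SUMO3)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in /SUMO5)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO3)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO1)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO2 and SUMO3)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO1 and SUMO2)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO1P1/SUMO5)"
    - "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in SUMO2)"
- task_name: "Succinylation (K)"
  candidate_residue: "K"
  annotation_keys:
    - "N6-succinyllysine"
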