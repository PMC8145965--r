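toxin_class	group
lipocalin	protease_inhibitor
serpin	protease_inhibitor
kazal	protease_inhibitor
kunitz	protease_inhibitor
trypsin_inhibitor	protease_inhibitor
peptidase_S1	proteolytic_enzyme
peptidase_S10	proteolytic_enzyme
dipeptidyl_peptidase4	proteolytic_enzyme
CAP	other_toxin
c_type_lectin	other_toxin
phospholipase_A2	other_toxin
carboxylesterase6	other_toxin
acid_phosphatase	other_toxin
antimicrobial_peptide	other_toxin
knottin_like	novel_peptide
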