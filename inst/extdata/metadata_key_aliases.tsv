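raw	harmonized
# raw keys are matched after lowercasing and mapping spaces/dashes to "_"
pepmass	precursor_mz
precursormz	precursor_mz
precursor_m/z	precursor_mz
prec_mz	precursor_mz
precursor_mass	precursor_mz
ms1_precursor_mz	precursor_mz
parentmass	parent_mass
parent	parent_mass
exactmass	parent_mass
exact_mass	parent_mass
neutral_mass	parent_mass
neutralmass	parent_mass
name	compound_name
compoundname	compound_name
compound	compound_name
molecule_name	compound_name
ion_mode	ionmode
ionisation_mode	ionmode
ionization_mode	ionmode
polarity	ionmode
precursortype	adduct
precursor_type	adduct
adducttype	adduct
adduct_type	adduct
inchi_key	inchikey
inchikey	inchikey
canonical_smiles	smiles
canonicalsmiles	smiles
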