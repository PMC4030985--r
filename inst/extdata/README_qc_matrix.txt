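qc_contact_energies_synthetic.csv

Synthetic quasi-chemical contact-energy matrix (20 x 20, three-letter
amino-acid codes, dimensionless). Built from the Kyte-Doolittle hydropathy
scale h: e_ab = -(h_a + h_b)/2 after rescaling h to [-1, 1], then shifted
to zero mean over the 210 unique pairs, so entries encode relative contact
propensities (hydrophobic pairs negative = attractive). This file is a
documented surrogate, NOT a statistical potential derived from structure
counts; substitute any symmetric matrix in the same format via
go_model(qc_matrix = ...). Regenerate with knotfold::qc_contact_matrix().
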