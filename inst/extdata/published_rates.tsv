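# Published phenotypic mutation rates (x 1e-7, Can-r mutants per cell division)
# of a haploid yeast Pol delta antimutator panel; transcribed printed values.
# Columns: can_msh6_e7 = antimutator allele combined with proofreading-deficient
# pol3-01 in MMR-proficient cells; can_pol3_01_msh6d_e7 = same allele with
# pol3-01 in msh6-null cells; can_eex_msh6d_e7 = allele with proofreading-
# proficient POL3 in msh6-null cells. qualifying = TRUE when the allele's
# proofreading-proficient msh6-null rate is within 2-fold of the POL3 msh6-null
# control (26), making it usable for the proofreading fold-effect average.
# These printed rates are formatting fixtures and fold-ratio inputs only; the
# underlying raw colony counts are unpublished.
allele	can_msh6_e7	can_pol3_01_msh6d_e7	can_eex_msh6d_e7	qualifying
POL3	4.9	NA	23	FALSE
pol3-01	135	NA	NA	FALSE
H879Y	53	11000	56	TRUE
Y808C	31	7700	39	TRUE
S968R	34	5200	23	TRUE
G204D	29	4500	54	TRUE
T711A	33	5900	22	TRUE
W821C	33	2600	33	TRUE
E594G	26	1700	15	TRUE
H620Y	15	3700	26	TRUE
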