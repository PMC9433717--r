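# Default predictor registry: 39 missense-relevant pathogenicity predictors.
# Per tool: `field` is the annotation locator (VEP CSQ sub-field name, or an
# INFO key when `location: info`), `direction` states which side of the
# threshold is pathogenic, and `reference_threshold` is the published decision
# cut-off on the tool's native scale. Comparators are strict: a score exactly
# at the threshold is classified benign.
SIFT:
  field: SIFT
  direction: lower_is_pathogenic
  reference_threshold: 0.01
  scope: protein
MutPred:
  field: MutPred
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
Polyphen2HDIV:
  field: Polyphen2HDIV
  direction: higher_is_pathogenic
  reference_threshold: 0.978
  scope: protein
Polyphen2HVAR:
  field: Polyphen2HVAR
  direction: higher_is_pathogenic
  reference_threshold: 0.978
  scope: protein
MutationAssessor:
  field: MutationAssessor
  direction: higher_is_pathogenic
  reference_threshold: 1.935
  scope: protein
Condel:
  field: Condel
  direction: higher_is_pathogenic
  reference_threshold: 0.98
  scope: protein
VEST4:
  field: VEST4
  direction: higher_is_pathogenic
  reference_threshold: 0.764
  scope: protein
MutationTaster2:
  field: MutationTaster2
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
FATHMM:
  field: FATHMM
  direction: lower_is_pathogenic
  reference_threshold: -4.14
  scope: protein
PROVEAN:
  field: PROVEAN
  direction: lower_is_pathogenic
  reference_threshold: -2.5
  scope: protein
MetaSVM:
  field: MetaSVM
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
MetaLR:
  field: MetaLR
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
M-CAP:
  field: M-CAP
  direction: higher_is_pathogenic
  reference_threshold: 0.025
  scope: protein
REVEL:
  field: REVEL
  direction: higher_is_pathogenic
  reference_threshold: 0.644
  scope: protein
MPC:
  field: MPC
  direction: higher_is_pathogenic
  reference_threshold: 1.36
  scope: protein
MTR:
  field: MTR
  direction: lower_is_pathogenic
  reference_threshold: 0.5
  scope: protein
PrimateAI:
  field: PrimateAI
  direction: higher_is_pathogenic
  reference_threshold: 0.79
  scope: protein
ClinPred:
  field: ClinPred
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
MISTIC:
  field: MISTIC
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
cVEP:
  field: cVEP
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
  excluded_from_multithreshold: true
  categorical_map:
    Benign: 0.0
    Likely_benign: 0.25
    Likely_pathogenic: 0.75
    Pathogenic: 1.0
MVP:
  field: MVP
  direction: higher_is_pathogenic
  reference_threshold: 0.7
  scope: protein
VARITY:
  field: VARITY
  direction: higher_is_pathogenic
  reference_threshold: 0.75
  scope: protein
MutFormer:
  field: MutFormer
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
EVE:
  field: EVE
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
MutScore:
  field: MutScore
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: protein
phastCons:
  field: phastCons
  direction: higher_is_pathogenic
  reference_threshold: 0.99
  scope: conservation
phyloP:
  field: phyloP
  direction: higher_is_pathogenic
  reference_threshold: 7.367
  scope: conservation
SiPhy:
  field: SiPhy
  direction: higher_is_pathogenic
  reference_threshold: 12.7
  scope: conservation
GERP:
  field: GERP
  direction: higher_is_pathogenic
  reference_threshold: 4.4
  scope: conservation
CDTS:
  field: CDTS
  direction: lower_is_pathogenic
  reference_threshold: 10.0
  scope: conservation
GWAVA:
  field: GWAVA
  direction: higher_is_pathogenic
  reference_threshold: 0.4
  scope: consequence_agnostic
FATHMM-MKL:
  field: FATHMM-MKL
  direction: higher_is_pathogenic
  reference_threshold: 0.5
  scope: consequence_agnostic
DANN:
  field: DANN
  direction: higher_is_pathogenic
  reference_threshold: 0.9
  scope: consequence_agnostic
Eigen:
  field: Eigen
  direction: higher_is_pathogenic
  reference_threshold: 1.0
  scope: consequence_agnostic
ReMM:
  field: ReMM
  direction: higher_is_pathogenic
  reference_threshold: 0.984
  scope: consequence_agnostic
CAPICE:
  field: CAPICE
  direction: higher_is_pathogenic
  reference_threshold: 0.02
  scope: consequence_agnostic
CADD:
  field: CADD
  direction: higher_is_pathogenic
  reference_threshold: 25.3
  scope: consequence_agnostic
CardioVAI:
  field: CardioVAI
  direction: higher_is_pathogenic
  reference_threshold: 2.0
  scope: disease_specific
CardioBoost:
  field: CardioBoost
  direction: higher_is_pathogenic
  reference_threshold: 0.9
  scope: disease_specific
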