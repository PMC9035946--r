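# Default engine parameters (versioned). Units: time in steps of 8 simulated
# hours (3 steps per day); concentrations in model units (AU); cell counts in
# agents. Receptor strings are l-bit integers. None of the rates below are
# published for the original platform; they are desk-scale modelling choices.
version: 1
l: 12
affinity:
  dMin: 8        # minimum complementary bits for binding
  alpha: 0.7     # per-missing-bit penalty
  pMax: 1.0
memoryRelax: 1   # memory lymphocytes bind with dMin - memoryRelax
mhcAffinity:     # MHC-peptide binding is far less specific than TCR/BCR matching
  dMin: 4
  alpha: 0.7
  pMax: 1.0
lattice:
  geometry: HEX2D
  side: 8
  boundary: PERIODIC
stepsPerDay: 3
pAspecific: 0.4  # fixed TLR-PAMP probability p'
pNonPamp: 0.1    # aspecific uptake of PAMP-free antigen
thymus:
  thetaPos: 4    # positive selection: min complementarity to any MHC
  thetaNeg: 10   # negative selection: complementarity to self complex that deletes
  nSelf: 8       # self peptides sampled per patient
  emigration: 0.5
ou:
  theta: 0.1
  sigma: 1.0
pools:           # homeostatic lineage means (cells)
  B: 120
  TH1: 60
  TH2: 60
  TC: 60
  TREG: 20
  NK: 20
  MONO: 20
  MAC: 30
  DC: 30
  MAST: 10
  NEU: 20
halfLife:        # steps
  naive: 240
  innate: 240
  plb: 30
  memory: 900
hayflick: 6
division:
  pDiv: 1.0      # blasts divide every 8-hour step while DUPLICATING
  fPLB: 0.25     # daughter fate: plasma cell
  fMem: 0.10     # daughter fate: memory cell
  pHyper: 0.3    # hypermutation probability per daughter (1 bit)
anergyWindow: 15 # steps a presenting B waits for help before anergy
tCell:
  pMem: 0.07     # ACTIVE T -> MEMORY per step
  pRest: 0.07    # ACTIVE T -> RESTING per step
apcRest: 0.1     # presenting APC -> RESTING per step
il4Threshold: 0.3  # local IL-4 (AU/site) for IgM -> IgG switch
pIgA: 0.002      # late IgG -> IgA switch per step
igRate: 1.0      # Ig secretion per plasma cell per step (AU)
igHalfLife: 63   # serum Ig half-life (21 days)
antigenHalfLife: 9  # bolus antigen half-life (3 days)
fields:
  D: 0.15       # cytokines act locally ...
  halfLife: 3   # ... and are short-lived
mast:
  pGrow: 0.02
  k: 1.0
clonotypeCap: 256
maxAgents: 20000
cytBaseline:     # total baseline field mass per species (AU)
  IL1: 0.5
  IL2: 0.5
  IL4: 0.1
  IL6: 0.5
  IL8: 0.5
  IL10: 0.5
  IL12: 0.5
  IL17: 0.5
  IL18: 0.5
  IL23: 0.5
  IFNG: 0.5
  IFNA1: 0.5
  IFNB1: 0.5
  TNFA: 0.5
  TGFB: 0.5
secretion:       # base secretion rates (AU per cell per step)
  - {type: TH2,  state: ACTIVE,        species: IL4,  rate: 1.0}
  - {type: TH2,  state: ACTIVE,        species: IL6,  rate: 0.5}
  - {type: TH2,  state: ACTIVE,        species: IL10, rate: 0.2}
  - {type: TH1,  state: ACTIVE,        species: IL2,  rate: 1.0}
  - {type: TH1,  state: ACTIVE,        species: IFNG, rate: 1.0}
  - {type: TH1,  state: ACTIVE,        species: IL17, rate: 0.2}
  - {type: TC,   state: ACTIVE,        species: IFNG, rate: 0.5}
  - {type: MAC,  state: PRESENTING_II, species: IL6,  rate: 0.5}
  - {type: MAC,  state: PRESENTING_II, species: TNFA, rate: 0.5}
  - {type: MAC,  state: PRESENTING_II, species: IL1,  rate: 0.3}
  - {type: MAC,  state: PRESENTING_II, species: IL12, rate: 0.3}
  - {type: DC,   state: PRESENTING_II, species: IL12, rate: 0.3}
  - {type: DC,   state: PRESENTING_II, species: IL8,  rate: 0.2}
  - {type: DC,   state: PRESENTING_II, species: IL18, rate: 0.2}
  - {type: DC,   state: PRESENTING_I,  species: IL12, rate: 0.3}
  - {type: MONO, state: PRESENTING_II, species: IL6,  rate: 0.3}
  - {type: NK,   state: RESTING,       species: IFNG, rate: 0.05}
  - {type: TREG, state: RESTING,       species: IL10, rate: 0.05}
  - {type: TREG, state: RESTING,       species: TGFB, rate: 0.05}
  - {type: MAST, state: RESTING,       species: IL4,  rate: 0.05}
  - {type: NEU,  state: RESTING,       species: IL8,  rate: 0.02}
hlaPool:         # 16 synthetic 12-bit haplotype stand-ins (no real alleles)
  [2893, 1741, 3346, 678, 2035, 3911, 157, 2482,
   1266, 3590, 821, 2957, 466, 1835, 3072, 1199]
antigens:        # synthetic 12-bit antigen definitions
  bacteria:   {epitope: 1385, peptides: [2742], pamp: true,  dose: 600}
  diphtheria: {epitope: 2217, peptides: [1558], pamp: true,  dose: 600}
  tetanus:    {epitope: 3461, peptides: [902],  pamp: true,  dose: 600}
  hib:        {epitope: 745,  peptides: [3214], pamp: true,  dose: 600}
  h1n1:       {epitope: 1930, peptides: [2651], pamp: true,  dose: 600}
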