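# Core adipocyte network: lumped glycolysis + oxPPP branch, TCA cycle with
# mitochondrial/cytosolic compartmentation, BCAA oxidation gated at BCKDH,
# propionyl-CoA anaplerosis, citrate shuttle and fatty acid synthesis sinks.
# Compartments: c cytosol, m mitochondria, x extracellular medium,
# f fresh-medium feed (unlabeled source), s sink. Carbons are numbered from
# C1 per standard biochemical convention (pyruvate C1 = carboxyl).
#
# Directives: #symmetric (rotationally symmetric species), #dilution
# (unlabeled dilution inflow species), #ratio (fixed flux ratio), #sink
# (biomass sinks).

#symmetric SUC.m FUM.m
#dilution CO2.x GLN.f GLU.f
#ratio v_oxppp v_glc_up 0.003
#sink C160.s C150.s C170.s

# glucose uptake and glycolysis (lumped; no glycolytic intermediates measured)
v_glc_up:  GLC.x (abcdef) -> GLC.c (abcdef)
v_oxppp:   GLC.c (abcdef) -> CO2.s (a) + P5P.s (bcdef)
v_glyc:    GLC.c (abcdef) -> PYR.c (cba) + PYR.c (def)
v_lac_sec: PYR.c (abc) -> LAC.x (abc)
v_ala_sec: PYR.c (abc) -> ALA.x (abc)

# pyruvate compartmentation and entry into the TCA cycle
v_pyrt:  PYR.c (abc) <-> PYR.m (abc)
v_pdh:   PYR.m (abc) -> CO2.s (a) + ACCOA.m (bc)
v_pc:    PYR.m (abc) + CO2.x (d) -> OAA.m (abcd)
v_me:    MAL.m (abcd) -> PYR.m (abc) + CO2.s (d)

# TCA cycle
v_cs:    OAA.m (abcd) + ACCOA.m (ef) -> CIT.m (dcbfea)
v_idh:   CIT.m (abcdef) -> AKG.m (abcde) + CO2.s (f)
v_akgdh: AKG.m (abcde) -> SUC.m (bcde) + CO2.s (a)
v_sdh:   SUC.m (abcd) <-> FUM.m (abcd)
v_fum:   FUM.m (abcd) <-> MAL.m (abcd)
v_mdh:   MAL.m (abcd) <-> OAA.m (abcd)

# citrate shuttle to cytosolic acetyl-CoA
v_citt:  CIT.m (abcdef) -> CIT.c (abcdef)
v_acl:   CIT.c (abcdef) -> ACCOA.c (ed) + OAA.c (fcba)
v_mdhc:  OAA.c (abcd) -> MAL.c (abcd)
v_malt:  MAL.c (abcd) <-> MAL.m (abcd)

# glutamine / glutamate: medium pools with dilution inflow plus simultaneous
# uptake and secretion; glutamate-alpha-ketoglutarate exchange
v_gln_dil: GLN.f (abcde) -> GLN.x (abcde)
v_gln_up:  GLN.x (abcde) -> GLN.c (abcde)
v_gln_sec: GLN.c (abcde) -> GLN.x (abcde)
v_gln_out: GLN.x (abcde) -> GLNW.s (abcde)
v_gls:     GLN.c (abcde) <-> GLU.c (abcde)
v_glu_dil: GLU.f (abcde) -> GLU.x (abcde)
v_glu_up:  GLU.x (abcde) -> GLU.c (abcde)
v_glu_sec: GLU.c (abcde) -> GLU.x (abcde)
v_glu_out: GLU.x (abcde) -> GLUW.s (abcde)
v_glut:    GLU.c (abcde) -> GLU.m (abcde)
v_gdh:     GLU.m (abcde) <-> AKG.m (abcde)

#ratio v_gln_dil v_gln_up 20
#ratio v_glu_dil v_glu_up 20

# BCAA oxidation, gated at BCKDH; lumped downstream steps draw the
# methylcrotonyl-CoA carboxylase carbon from the unlabeled CO2 pool
v_leu_up:   LEU.x (abcdef) -> LEU.c (abcdef)
v_bcat_l:   LEU.c (abcdef) <-> KIC.c (abcdef)
v_bckdh_l:  KIC.c (abcdef) + CO2.x (g) -> CO2.s (a) + ACCOA.m (bc) + ACCOA.m (de) + ACCOA.m (fg)
v_val_up:   VAL.x (abcde) -> VAL.c (abcde)
v_bcat_v:   VAL.c (abcde) <-> KIV.c (abcde)
v_bckdh_v:  KIV.c (abcde) -> CO2.s (a) + CO2.s (e) + PROP.m (bcd)
v_ile_up:   ILE.x (abcdef) -> ILE.c (abcdef)
v_ileox:    ILE.c (abcdef) -> CO2.s (a) + ACCOA.m (bc) + PROP.m (def)

# propionyl-CoA: succinyl-CoA anaplerosis and odd-chain FA priming
v_pcc:    PROP.m (abc) + CO2.x (d) -> SUC.m (abcd)
v_propt:  PROP.m (abc) -> PROP.c (abc)

# fatty acid synthesis sinks (measured products)
v_fas16: ACCOA.c (ab) + ACCOA.c (cd) + ACCOA.c (ef) + ACCOA.c (gh) + ACCOA.c (ij) + ACCOA.c (kl) + ACCOA.c (mn) + ACCOA.c (op) -> C160.s (abcdefghijklmnop)
v_fas15: PROP.c (abc) + ACCOA.c (de) + ACCOA.c (fg) + ACCOA.c (hi) + ACCOA.c (jk) + ACCOA.c (lm) + ACCOA.c (no) -> C150.s (abcdefghijklmno)
v_fas17: PROP.c (abc) + ACCOA.c (de) + ACCOA.c (fg) + ACCOA.c (hi) + ACCOA.c (jk) + ACCOA.c (lm) + ACCOA.c (no) + ACCOA.c (pq) -> C170.s (abcdefghijklmnopq)
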