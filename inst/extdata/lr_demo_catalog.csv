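pair_id,ligand_subunits,receptor_subunits
IL13_IL13RA1,IL13,IL13RA1|IL4R
IL13_IL13RA2,IL13,IL13RA2
IL4_IL4R,IL4,IL4R|IL2RG
IL5_IL5RA,IL5,IL5RA|CSF2RB
TSLP_TSLPR,TSLP,CRLF2|IL7R
IL33_ST2,IL33,IL1RL1|IL1RAP
TGFB1_TGFBR,TGFB1,TGFBR1|TGFBR2
TNF_TNFRSF1A,TNF,TNFRSF1A
TNF_TNFRSF1B,TNF,TNFRSF1B
IFNG_IFNGR,IFNG,IFNGR1|IFNGR2
CCL26_CCR3,CCL26,CCR3
CCL11_CCR3,CCL11,CCR3
CCL2_CCR2,CCL2,CCR2
CXCL12_CXCR4,CXCL12,CXCR4
CXCL8_CXCR1,CXCL8,CXCR1
CSF1_CSF1R,CSF1,CSF1R
CSF2_CSF2R,CSF2,CSF2RA|CSF2RB
KITLG_KIT,KITLG,KIT
VEGFA_KDR,VEGFA,KDR
VEGFA_FLT1,VEGFA,FLT1
PDGFB_PDGFRB,PDGFB,PDGFRB
EGF_EGFR,EGF,EGFR
HBEGF_EGFR,HBEGF,EGFR
FGF2_FGFR1,FGF2,FGFR1
MADCAM1_ITGA4B7,MADCAM1,ITGA4|ITGB7
VCAM1_ITGA4B1,VCAM1,ITGA4|ITGB1
ICAM1_ITGALB2,ICAM1,ITGAL|ITGB2
CD40LG_CD40,CD40LG,CD40
NGF_NTRK1,NGF,NTRK1
ANGPT1_TEK,ANGPT1,TEK
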