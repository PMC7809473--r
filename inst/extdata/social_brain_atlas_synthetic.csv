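# Synthetic stand-in for the published 36-region social brain atlas table.
# Region set follows the structures named in the source meta-analytic atlas
# (four clusters); coordinates are plausible placeholder MNI values, NOT the
# published ones. Region order is fixed (clusters in canonical order, regions
# alphabetical within cluster) and defines downstream matrix column order.
name,hemisphere,x,y,z,cluster
FG_L,left,-42,-50,-20,visual_sensory
FG_R,right,42,-50,-20,visual_sensory
MTV5_L,left,-46,-70,4,visual_sensory
MTV5_R,right,46,-70,4,visual_sensory
pSTS_L,left,-52,-40,6,visual_sensory
pSTS_R,right,52,-40,6,visual_sensory
AM_L,left,-22,-4,-18,limbic
AM_R,right,22,-4,-18,limbic
HC_L,left,-26,-16,-16,limbic
HC_R,right,26,-16,-16,limbic
NAC_L,left,-10,10,-8,limbic
NAC_R,right,10,10,-8,limbic
rACC,midline,0,38,8,limbic
vmPFC,midline,0,46,-14,limbic
AI_L,left,-34,20,-2,intermediate
AI_R,right,34,20,-2,intermediate
aMCC,midline,0,24,30,intermediate
Cereb_L,left,-26,-74,-32,intermediate
Cereb_R,right,26,-74,-32,intermediate
IFG_L,left,-48,26,6,intermediate
IFG_R,right,48,26,6,intermediate
SMA,midline,0,6,58,intermediate
SMG_L,left,-58,-44,32,intermediate
SMG_R,right,58,-44,32,intermediate
dmPFC,midline,0,52,24,higher_associative
FP_L,left,-24,58,10,higher_associative
FP_R,right,24,58,10,higher_associative
MTG_L,left,-58,-26,-8,higher_associative
MTG_R,right,58,-26,-8,higher_associative
PCC,midline,0,-36,40,higher_associative
pMCC,midline,0,-16,42,higher_associative
Prec,midline,0,-60,38,higher_associative
TP_L,left,-44,14,-32,higher_associative
TP_R,right,44,14,-32,higher_associative
TPJ_L,left,-50,-56,22,higher_associative
TPJ_R,right,50,-56,22,higher_associative
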