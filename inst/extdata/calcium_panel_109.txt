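# Neuronal calcium-signalling gene panel (109 genes), one symbol per line.
# Editable convention used for the panel z-score heatmap; replace freely.
# voltage-gated calcium channel subunits
CACNA1A
CACNA1B
CACNA1C
CACNA1D
CACNA1E
CACNA1G
CACNA1H
CACNA1I
CACNA2D1
CACNA2D2
CACNB1
CACNB2
CACNB3
CACNB4
CACNG2
# store-operated entry machinery and TRPC channels
STIM1
STIM2
ORAI1
ORAI2
ORAI3
TRPC1
TRPC3
TRPC4
TRPC5
TRPC6
# ER release channels
ITPR1
ITPR2
ITPR3
RYR1
RYR2
RYR3
# pumps
ATP2A1
ATP2A2
ATP2A3
ATP2B1
ATP2B2
ATP2B3
ATP2B4
ATP2C1
# exchangers and mitochondrial uptake
SLC8A1
SLC8A2
SLC8A3
SLC24A2
MCU
MICU1
MICU2
VDAC1
# calcium buffers and sensors
CALB1
CALB2
PVALB
S100B
HPCA
HPCAL1
NCS1
CABP1
# calmodulins, CaM kinases, calcineurin
CALM1
CALM2
CALM3
CAMK1
CAMK2A
CAMK2B
CAMK2D
CAMK2G
CAMK4
CAMKK1
CAMKK2
PPP3CA
PPP3CB
PPP3R1
# calcium-regulated transcription and plasticity effectors
CREB1
CREBBP
NFATC1
NFATC2
NFATC3
NFATC4
MEF2C
BDNF
EGR1
FOS
JUN
ARC
# phospholipase C / PKC / IP3 kinases
PLCB1
PLCB4
PLCG1
PLCD1
PRKCA
PRKCB
PRKCG
ITPKA
ITPKB
# calcium-permeable receptors
GRIN1
GRIN2A
GRIN2B
GRIA1
GRIA2
GRM1
GRM5
CHRNA7
P2RX7
HTR2A
# ER store and accessory proteins
CASQ1
CASQ2
WFS1
CIB1
TRPV1
TRPM4
P2RX4
RCAN1
VSNL1
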