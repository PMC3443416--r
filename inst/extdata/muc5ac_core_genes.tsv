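symbol	category
TFF3	mucus_component
TFF1	mucus_component
SPDEF	differentiation_transcription_factor
FOXA3	differentiation_transcription_factor
SOX2	differentiation_transcription_factor
KLF4	differentiation_transcription_factor
HES1	differentiation_pathway_or_mediator
TSTA3	differentiation_pathway_or_mediator
LRRFIP2	differentiation_pathway_or_mediator
KRAS	differentiation_pathway_or_mediator
MAPK13	differentiation_pathway_or_mediator
RPS6KA3	differentiation_pathway_or_mediator
CTSC	differentiation_pathway_or_mediator
SERPINB4	differentiation_pathway_or_mediator
PLA2G4A	differentiation_pathway_or_mediator
AGR2	posttranslational_modification
GNE	posttranslational_modification
GALNT4	posttranslational_modification
GALNT7	posttranslational_modification
GALNT12	posttranslational_modification
PDIA5	posttranslational_modification
FUT3	posttranslational_modification
FUT6	posttranslational_modification
ST6GAL1	posttranslational_modification
ST8SIA1	posttranslational_modification
CHST6	posttranslational_modification
GALNT5	posttranslational_modification
GALNT6	posttranslational_modification
MIA3	vesicle_transport
SURF4	vesicle_transport
KDELR2	vesicle_transport
KDELR3	vesicle_transport
ITSN1	vesicle_transport
ERGIC1	vesicle_transport
CKAP4	vesicle_transport
GOSR1	vesicle_transport
SYNJ2BP	vesicle_transport
MPPE1	vesicle_transport
SEC31A	vesicle_transport
ARF4	vesicle_transport
VPS13D	vesicle_transport
SEC22B	vesicle_transport
TPD52	vesicle_transport
CREB3L1	er_stress
EDEM3	er_stress
XBP1	er_stress
EIF2AK3	er_stress
SYTL2	secretory_granule
RAB3D	secretory_granule
SCIN	secretory_granule
STXBP6	secretory_granule
RAB27B	secretory_granule
SYTL4	secretory_granule
SYTL5	secretory_granule
GSN	secretory_granule
RIMS1	secretory_granule
CASK	secretory_granule
MYO5B	secretory_granule
MYO5C	secretory_granule
PCLO	secretory_granule
PAM	secretory_granule
ATP6V0A4	secretory_granule
KIF5B	secretory_granule
CDC42EP5	secretory_granule
PRSS23	secretion_regulator
PLCE1	secretion_regulator
DGKA	secretion_regulator
ITPR3	secretion_regulator
PRKCD	secretion_regulator
SLC12A2	ion_channel
CLCA2	ion_channel
SCNN1A	ion_channel
GABRP	ion_channel
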