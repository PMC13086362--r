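# Default C3/C4 mixing configuration.
# Regional Caucasus end-members: enamel cut-offs from published C3/C4 plant
# surveys pushed through the Suess correction (+1.5 permil) and the ruminant
# diet-to-enamel enrichment (+14.1 permil); collagen expectations from the
# same plant values with a +5 permil diet-to-collagen offset. The enamel
# ceiling for purely water-stressed C3 diets is -6.7 permil.
suess_correction: 1.5
enamel_enrichment_epsilon: 14.1
collagen_diet_offset: 5.0
enamel_c3_endmember: -11.58
enamel_c3_sd: 3.00
enamel_c4_endmember: 4.18
enamel_c4_sd: 1.17
collagen_c3_endmember: -20.3
collagen_c4_endmember: -6.3
water_stressed_c3_limit_enamel: -6.7
enrichment_form: linear_addition
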