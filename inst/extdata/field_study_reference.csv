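source,fawn_mortality,adult_mortality,fawn_risk_weight,adult_risk_weight,delta4_nursery,delta4_nursery_low,delta4_nursery_high,delta4_adult,delta4_adult_low,delta4_adult_high
bear,0.01,0.00,0.12,0.00,0.65,0.64,0.65,0.85,0.85,0.86
bobcat,0.02,0.00,0.21,0.00,0.44,0.43,0.46,0.70,0.69,0.71
coyote,0.04,0.009,0.37,0.15,0.41,0.40,0.42,0.66,0.65,0.66
wolf,0.01,0.01,0.08,0.46,0.61,0.60,0.62,0.86,0.85,0.87
human,0.03,0.01,0.21,0.38,0.71,0.71,0.72,0.51,0.51,0.51
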