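factor,comparison,case_exposed,case_unexposed,control_exposed,control_unexposed
region,outlying vs primary,328,146,1215,1028
insurance,medicaid vs insured,198,257,660,1528
insurance,none vs insured,19,257,55,1528
financial_screen,ever vs never,73,401,122,2121
education,less vs more,231,243,740,1503
ethnicity,other vs white,80,394,207,2036
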