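indicator,item_id,a_plus,rep_plus,a_minus,rep_minus,printed_variation
Sport activity - frequency,QB1,57.04,FI - Finland,14.96,Education 15-,281.3
Physical activity - frequency,QB2,74.98,NL - The Netherlands,14.89,PT - Portugal,403.5
Vigorous physical activity - days last week,QB3,32.98,FI - Finland,9.66,PT - Portugal,241.4
Vigorous physical activity - how much time,QB4,43.46,LV - Latvia,9.88,PT - Portugal,339.9
Moderate physical activity - days last week,QB5,49.02,NL - The Netherlands,9.64,PT - Portugal,408.6
Moderate physical activity - how much time,QB6,40.48,EE - Estonia,9.97,PT - Portugal,305.9
Walked at least 10 minutes - days last week,QB7,74.54,ES - Spain,43.64,PL - Poland,70.8
Walked at least 10 minutes - how much time,QB8,39.22,LV - Latvia,18.18,CY - Cyprus,115.7
Time spent sitting - usual day,QB9,65.60,MT - Malta,43.73,Social class Refusal,50.0
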