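reference,altitude_m,hr_ratio,sa_max_pct,hb_ratio,days
Moore et al.,4350,0.924,82,1.23,19
Pugh et al.,4600,0.928,,,30-90
Pugh et al.,5800,0.756,57,1.47,60-90
Klausen et al.,3800,0.89,,,25
Klausen et al.,4340,0.906,,,16
Vogel et al.,4300,0.978,79.4,1.07,3
Vogel et al.,4300,0.95,81.7,1.11,17
Dill & Adams,3090,0.944,,,17
Vogel et al.,4350,0.924,,,10
Cerretelli,5350,0.87,,1.37,
Horstman et al.,4300,0.963,,,15
Saltin et al.,4300,0.946,79.5,1.13,15
Dill et al.; Klausen et al.,3800,0.899,,1.08,20
Vogel et al.,4600,0.873,,,3
Sutton et al.,6100,0.82,61,1.2,
Sutton et al.,7620,0.73,59,1.26,
Sutton et al.,8840,0.70,49,1.26,
Christensen & Forbes,5340,0.695,70,1.5,9-10
Richalet,5000,0.859,,,21
Richalet et al.,4350,0.952,,,8
Richalet et al.,4800,0.901,92,,21
West et al.; Winslow et al.,6300,0.82,61,1.29,
West et al.; Winslow et al.,8050,0.719,57,1.27,
West et al.; Winslow et al.,8848,0.741,49,1.29,
Young et al.,4300,0.874,,,15
Antezana et al.,6542,0.843,68,1.13,7
Richalet et al.; Robach et al.,5000,0.85,77,1.1,2-6
Richalet et al.; Robach et al.,6000,0.785,72,1.07,9-12
Richalet et al.; Robach et al.,7000,0.75,68,1.14,15-19
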