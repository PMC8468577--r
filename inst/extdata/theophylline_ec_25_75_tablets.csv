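name,tablet,pathway,desirability,api_mg,excipient_mg
real,T25E75-01,-,NA,89.8,320.4
B1,T25E75-01,Sta/RB/UC/EC18/G1.7/KM(9),1.000,88.6,316.2
B4,T25E75-01,Ref/PFF/UC/EC11/G2.2/KM(11),1.000,89.5,322.6
D,T25E75-01,-,NA,88.6,316.2
G,T25E75-01,-,NA,88.6,316.2
real,T25E75-03,-,NA,86.9,329.5
B1,T25E75-03,Sta/RB/UC/EC18/G1.7/KM(9),0.982,90.0,329.0
B2,T25E75-03,Sta/RB/UC/G1.3/EC14/KM(7),0.991,89.3,329.6
B3,T25E75-03,Sta/UC/UC/EC13/G2.7/KM(12),0.958,91.1,327.6
B4,T25E75-03,Ref/PFF/UC/EC11/G2.2/KM(11),0.946,91.5,327.5
C1,T25E75-03,Sta/RB/UC/EC17/G1.5/KM(12),0.823,78.6,329.1
C2,T25E75-03,Sta/UC/UC/EC13/G2.5/KM(12),0.904,93.0,326.2
API1,T25E75-03,Ref/PFF/UC/G3.3/EC13/KM(12),0.985,84.1,332.5
API2,T25E75-03,Ref/PFF/UC/EC16/G3.7/KM(12),0.789,96.3,322.4
T1,T25E75-03,Ref/RB/NLM/G1.9/EC18/KM(9),1.000,86.2,326.6
T2,T25E75-03,Sta/RB/UC/EC18/G1.7/KM(10),1.000,86.3,326.6
T3,T25E75-03,Ref/RB/NLM/G1.9/EC18/KM(11),0.902,80.6,325.2
T4,T25E75-03,Ref/PFF/NLM/EC15/G2.7/KM(12),0.801,96.1,323.8
T5,T25E75-03,Ref/PFF/UC/EC11/G2.3/KM(10),0.700,98.4,322.0
T6,T25E75-03,Ref/UC/NLM/EC2/G2.3/MaE-iB//MaE,0.600,98.2,305.8
T7,T25E75-03,Ref/UC/NLM/ECequalize/G2.1/KM(11),0.506,73.3,329.2
T8,T25E75-03,Ref/UC/NLM/EC2/G2.3/MaE//MiE,0.405,98.2,286.5
T9,T25E75-03,Ref/UC/NLM/EC2/G2.3/MaE//Y-iB,0.326,98.2,280.8
T10,T25E75-03,Ref/UC/NLM/ECequalize/G2.3/KM(6),0.202,100.9,280.9
T11,T25E75-03,Ref/PFF/NLM/ECequalize/G2.1/KM(4),0.127,73.0,275.5
D,T25E75-03,-,NA,88.6,316.2
G,T25E75-03,-,NA,88.6,316.2
real,T25E75-05,-,NA,86.1,331.4
B1,T25E75-05,Sta/RB/UC/EC18/G1.7/KM(9),0.955,90.4,330.3
B4,T25E75-05,Ref/PFF/UC/EC11/G2.2/KM(11),0.928,91.4,329.4
D,T25E75-05,-,NA,88.6,316.2
G,T25E75-05,-,NA,88.6,316.2
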