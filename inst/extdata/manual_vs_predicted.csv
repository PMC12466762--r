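cattle_id,trait,gt_cm,pred_cm,re_printed_pct
1,body_height,125,126.5,1.20
1,hip_height,132.5,134.2,1.31
1,body_length,139.5,137.1,1.78
1,cannon_circumference,19.5,19.9,2.36
2,body_height,143,141.8,0.86
2,hip_height,145.5,147.2,1.22
2,body_length,165,168.5,2.11
2,cannon_circumference,21,21.6,2.94
3,body_height,138.5,141.4,2.10
3,hip_height,146.5,145.1,0.98
3,body_length,173.5,171.2,1.30
3,cannon_circumference,22,22.7,3.45
4,body_height,134,131.3,1.98
4,hip_height,136,137.2,0.86
4,body_length,173.5,177.9,2.56
4,cannon_circumference,18,17.5,2.77
5,body_height,131.5,134.5,2.34
5,hip_height,134.2,136.2,1.49
5,body_length,150,152.8,1.92
5,cannon_circumference,20,19.2,3.90
6,body_height,146,147.4,0.97
6,hip_height,150,151.7,1.16
6,body_length,170,172.4,1.45
6,cannon_circumference,23,23.7,3.12
7,body_height,131.5,132.7,0.90
7,hip_height,134.2,137.6,2.56
7,body_length,149.5,151.9,1.63
7,cannon_circumference,20,20.8,4.10
8,body_height,125.5,124.2,1.10
8,hip_height,132,135.1,2.39
8,body_length,146,143.5,1.72
8,cannon_circumference,20,19.3,3.56
9,body_height,138,141.4,2.50
9,hip_height,142,143.6,1.10
9,body_length,173,169.8,1.86
9,cannon_circumference,24,25,4.54
10,body_height,140,142,1.45
10,hip_height,146,144.2,1.25
10,body_length,151,153.7,1.77
10,cannon_circumference,20.5,21.1,2.97
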