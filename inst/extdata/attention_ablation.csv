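model,precision,recall,ap50,ap5095,parameters_m,gflops
YOLOv8n,0.8891,0.8753,0.9096,0.8371,3.09,8.5
YOLOv8n+DRAMiTransformer,0.8990,0.8731,0.9131,0.8440,3.13,8.9
YOLOv8n+MHSA-C2f,0.8761,0.8773,0.9101,0.8362,3.14,8.5
YOLOv8n+CASimAM,0.8902,0.8760,0.8973,0.8342,3.10,8.5
YOLOv8n+DRAMiTransformer+MHSA-C2f,0.8895,0.8856,0.9223,0.8470,3.18,9.0
YOLOv8n+DRAMiTransformer+CASimAM,0.9021,0.8712,0.9083,0.8401,3.14,9.0
YOLOv8-DMC-pose,0.8820,0.8810,0.9310,0.8680,3.44,9.4
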