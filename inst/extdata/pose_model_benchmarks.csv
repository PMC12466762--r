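model,precision,recall,ap50,ap5095,parameters_m,gflops
YOLOv5-pose,0.8756,0.8850,0.8877,0.8298,3.09,8.5
YOLOv8n-pose,0.8891,0.8753,0.9096,0.8371,3.09,8.5
YOLOv8s-pose,0.8970,0.8750,0.9100,0.8420,11.42,29.6
YOLOv11-pose,0.8986,0.8868,0.9117,0.8500,2.62,6.6
YOLOv8-DMC-pose,0.8820,0.8810,0.9310,0.8680,3.44,9.4
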