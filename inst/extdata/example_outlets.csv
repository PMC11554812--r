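id,x_mm,y_mm,z_mm,radius_mm,resistance_Pa_s_per_m3
1,5,5,10,1.4,0
2,15,5,10,1.1,0
3,5,15,10,0.8,0
4,15,15,10,0.6,0
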