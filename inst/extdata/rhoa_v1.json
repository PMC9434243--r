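{"osteophyte_grade1_mm2":{"acetabular":1,"superior_femoral":1,"inferior_femoral":1},"osteophyte_grade2_mm2":{"acetabular":10,"superior_femoral":19,"inferior_femoral":15},"osteophyte_grade3_mm2":50,"jsn_grade3_mjsw_mm":1.5,"jsn_grade1_adjusted_cut":2.301,"jsn_grade2_adjusted_cut":1.739,"composite_cuts":[0,1,2,2,3,3,3,4,4,4,4,4,4],"height_model":{"slope_mm_per_cm":0.012,"reference_height_cm":170.1},"config_version":"rhoa_v1"}
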