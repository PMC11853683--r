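crista_id,length_um,n_segments,cjs_per_segment,cj_ends,class,spanning,branched,cj_diameter_nm,seg_length_total_um
C1,0.41,3,2.3,both,narrow,TRUE,TRUE,16.5,0.55
C2,0.45,2,2.0,both,narrow,TRUE,FALSE,18.0,0.45
C3,0.49,2,2.5,both,narrow,TRUE,FALSE,15.0,0.49
C4,0.53,2,1.9,both,narrow,TRUE,FALSE,17.5,0.53
C5,0.58,2,2.0,both,narrow,TRUE,FALSE,19.0,0.58
C6,0.63,3,2.7,both,narrow,TRUE,TRUE,16.0,0.85
C7,0.68,1,2.0,one,narrow,FALSE,FALSE,14.0,0.68
C8,0.73,1,1.5,one,narrow,FALSE,FALSE,18.5,0.73
C9,0.78,2,1.0,one,narrow,TRUE,FALSE,22.0,0.78
C10,0.85,4,2.3,both,narrow,TRUE,TRUE,17.0,1.45
C11,0.98,1,2.0,one,narrow,FALSE,FALSE,16.0,0.98
C12,1.12,5,2.5,both,narrow,TRUE,TRUE,20.0,2.30
C13,1.25,5,3.0,both,narrow,TRUE,TRUE,15.5,2.56
C14,1.38,3,2.6,both,narrow,TRUE,TRUE,17.0,1.86
C15,1.44,5,2.8,both,narrow,TRUE,TRUE,12.0,2.95
C16,1.46,1,2.0,one,narrow,FALSE,FALSE,21.0,1.46
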