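patient_id,arm,clin_essdai_base,clin_essdai_fu,esspri_base,esspri_fu,schirmer_base,schirmer_fu,oss_base,oss_fu,uwsf_base,uwsf_fu,hocevar_base,hocevar_fu,igg_base,igg_fu,rf_base,rf_fu,age
p01,treatment,12,6,7.2,5.5,3,9,6,3,0.15,0.22,24,16,16.4,14.1,85,55,54
p02,treatment,8,6,6.8,6.5,10,8,2,2,0.30,0.31,18,17,13.2,13.0,0,0,61
p03,treatment,10,7,8.0,6.4,4,4,5,3,0.00,0.05,30,21,19.8,17.5,120,80,47
p04,treatment,6,6,5.5,5.4,12,11,1,1,0.25,0.24,12,12,11.0,11.2,35,36,66
p05,treatment,14,9,7.5,6.0,2,8,8,5,0.10,0.14,,,21.5,18.9,200,140,58
p06,placebo,11,10,7.0,6.8,3,4,6,6,0.18,0.17,22,21,15.9,15.6,90,88,52
p07,placebo,9,8,6.5,6.6,9,9,2,3,0.28,0.26,16,18,12.8,13.1,0,0,63
p08,placebo,13,9,8.2,7.9,5,4,7,6,0.05,0.06,28,27,18.3,18.0,150,150,49
p09,placebo,7,7,5.8,5.2,11,12,1,1,0.33,0.35,,,10.9,10.7,40,42,57
p10,placebo,10,10,7.8,7.7,2,2,9,8,0.12,0.11,26,26,17.1,17.4,110,105,60
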