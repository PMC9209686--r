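# Column-name mapping: internal_name: file_column.
# Only names that differ from the internal scheme need listing; per-eye
# Schirmer/OSS exports may map *_left / *_right pairs, which are averaged
# on read.
patient_id: subject
arm: treatment_group
clin_essdai_base: clinessdai_w0
clin_essdai_fu: clinessdai_w24
schirmer_base_left: schirmer_os_w0
schirmer_base_right: schirmer_od_w0
schirmer_fu_left: schirmer_os_w24
schirmer_fu_right: schirmer_od_w24
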