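country_code,prevalence_per_1000,source
SK,0.53,Behunova_et_al
SI,0.74,Kokalj_et_al
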