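mgo_codes: A02AA02
sg_codes: A06AB06
krr_products:
- mashiningan
- daiokanzoto
- otsujito
- bofutsushosan
- tokakujokito
- keishikashakuyakudaioto
- junchoto
- crude_daio
- tsudosan
- choijokito
- jidabokuippo
- daisaikoto
- daiobotampito
- sanoshashinto
- inchinkoto
- jizusoippo
- daijokito
daikenchuto_codes: daikenchuto
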