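taxonID	vernacularName
s-bmus	blue whale
s-pgla	blue whaler
s-mgun	bahama mockingbird
s-mpol	northern mockingbird
s-mmac	hood mockingbird
s-mgil	tropical mockingbird
s-msat	chalk-browed mockingbird
s-mtri	white-banded mockingbird
s-mthe	chilean mockingbird
s-mcae	blue mockingbird
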