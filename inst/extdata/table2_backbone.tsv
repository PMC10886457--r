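taxonID	scientificName	rank	parentID
k-anim	Animalia	kingdom
k-chro	Chromista	kingdom
p-chor	Chordata	phylum	k-anim
p-arth	Arthropoda	phylum	k-anim
p-baci	Bacillariophyta	phylum	k-chro
c-mamm	Mammalia	class	p-chor
c-elas	Elasmobranchii	class	p-chor
c-aves	Aves	class	p-chor
c-acti	Actinopterygii	class	p-chor
c-inse	Insecta	class	p-arth
c-tril	Trilobita	class	p-arth
c-bacl	Bacillariophyceae	class	p-baci
o-arti	Artiodactyla	order	c-mamm
o-carc	Carcharhiniformes	order	c-elas
o-pass	Passeriformes	order	c-aves
o-myct	Myctophiformes	order	c-acti
o-step	Stephanoberyciformes	order	c-acti
o-dipt	Diptera	order	c-inse
o-hyme	Hymenoptera	order	c-inse
o-phac	Phacopida	order	c-tril
o-navi	Naviculales	order	c-bacl
f-bala	Balaenopteridae	family	o-arti
f-carc	Carcharhinidae	family	o-carc
f-mimi	Mimidae	family	o-pass
f-myct	Myctophidae	family	o-myct
f-mela	Melamphaidae	family	o-step
f-hybo	Hybotidae	family	o-dipt
f-ceci	Cecidomyiidae	family	o-dipt
f-vesp	Vespidae	family	o-hyme
f-dalm	Dalmanitidae	family	o-phac
f-stau	Stauroneidaceae	family	o-navi
g-bala	Balaenoptera	genus	f-bala
g-prio	Prionace	genus	f-carc
g-mimu	Mimus	genus	f-mimi
g-mela	Melanotis	genus	f-mimi
g-boli	Bolinichthys	genus	f-myct
g-mlph	Melamphaes	genus	f-mela
g-cher	Chersodromia	genus	f-hybo
g-cont	Conterinia	genus	f-ceci
g-pseu	Pseudepipona	genus	f-vesp
g-prod	Prodalmanitina	genus	f-dalm
g-stau	Stauroneis	genus	f-stau
s-bmus	Balaenoptera musculus	species	g-bala
s-pgla	Prionace glauca	species	g-prio
s-mgun	Mimus gundlachii	species	g-mimu
s-mpol	Mimus polyglottos	species	g-mimu
s-mmac	Mimus macdonaldi	species	g-mimu
s-mgil	Mimus gilvus	species	g-mimu
s-msat	Mimus saturninus	species	g-mimu
s-mtri	Mimus triurus	species	g-mimu
s-mthe	Mimus thenca	species	g-mimu
s-mcae	Melanotis caerulescens	species	g-mela
s-bnik	Bolinichthys nikolayi	species	g-boli
s-mnik	Melamphaes nikolayi	species	g-mlph
s-cnik	Chersodromia nikolayi	species	g-cher
s-conik	Conterinia nikolayi	species	g-cont
s-pnik	Pseudepipona nikolayi	species	g-pseu
s-prnik	Prodalmanitina nikolayevi	species	g-prod
s-snik	Stauroneis nikolayi	species	g-stau
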