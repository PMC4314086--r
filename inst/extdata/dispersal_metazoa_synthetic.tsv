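species	taxon	chromosome_system	dispersing_sex
Homo sapiens	mammal	XY	male
Pan troglodytes	mammal	XY	male
Macaca mulatta	mammal	XY	male
Papio cynocephalus	mammal	XY	male
Canis lupus	mammal	XY	male
Lycaon pictus	mammal	XY	female
Cervus elaphus	mammal	XY	male
Ovis canadensis	mammal	XY	male
Halichoerus grypus	mammal	XY	male
Mirounga leonina	mammal	XY	male
Phoca vitulina	mammal	XY	male
Rattus norvegicus	mammal	XY	male
Microtus oeconomus	mammal	XY	male
Myotis myotis	mammal	XY	male
Parus major	bird	ZW	female
Ficedula albicollis	bird	ZW	female
Hirundo rustica	bird	ZW	female
Passer domesticus	bird	ZW	female
Uria aalge	bird	ZW	female
Larus argentatus	bird	ZW	female
Strix aluco	bird	ZW	female
Taeniopygia guttata	bird	ZW	female
Gallus gallus	bird	ZW	female
Anser anser	bird	ZW	female
Anas platyrhynchos	bird	ZW	male
Drosophila melanogaster	insect	XY	male
Drosophila pseudoobscura	insect	XY	male
Musca domestica	insect	XY	male
Heliconius melpomene	insect	ZW	female
Melitaea cinxia	insect	ZW	female
Papilio machaon	insect	ZW	male
Chorthippus parallelus	insect	XO	male
Schistocerca gregaria	insect	XO	female
Gryllus campestris	insect	XO	female
Operophtera brumata	insect	ZO	male
Thaumetopoea pityocampa	insect	ZO	male
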