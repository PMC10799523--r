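aa_metabolism	Synthetic amino acid metabolism set	glycine	isoleucine	asparagine	glutamate	glutamine	histidine	tyrosine	valine	threonine	phenylalanine	tryptophan	aspartate	arginine	ornithine	cystine	kynurenine	oxoproline
acylcarnitine_shuttle	Synthetic carnitine shuttle set	butyrylcarnitine	myristoylcarnitine	acetylcarnitine	octanylcarnitine	propionylcarnitine	carnitine
tca_and_pyruvate	Synthetic central carbon metabolism set	pyruvate	fumarate	succinate	citrate	malate	oxaloacetate	lactate
lipid_signalling	Synthetic lipid mediator set	sphingosine 1 phosphate	docosahexanoate	eicosapentanoate	linoleate	linolenate	arachidonate	gamma linolenicate a
purine_degradation	Synthetic purine degradation set	urate	hypoxanthine	xanthine	inosine
hexose_pool	Synthetic hexose set	glucose	fructose	galactose	mannose
osmolytes	Synthetic osmolyte set	creatinine	urea	choline	betaine	taurine	trimethyl n oxide
nucleotide_pool	Synthetic nucleotide set	adenosine	guanosine	cytidine	uridine	thymidine	amp	gmp	ump	cmp	imp
bile_acids	Synthetic bile acid set	cholate	deoxycholate	chenodeoxycholate	glycocholate	taurocholate	lithocholate
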