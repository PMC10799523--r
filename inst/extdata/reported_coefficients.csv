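model,metabolite,coefficient
mortality,Glycine,-0.011
mortality,Isoleucine,-0.124
mortality,Asparagine,0.035
mortality,Glutamate,-0.012
mortality,Tyrosine,0.090
mortality,Pyruvate,-0.065
mortality,Fumarate,0.083
mortality,Oxoproline,0.101
mortality,Butyrylcarnitine,0.028
mortality,Docosahexanoate,-0.036
mortality,Glutamine,0.029
mortality,Histidine,0.111
mortality,Myristoylcarnitine,0.055
mortality,Sphingosine 1 phosphate,-0.049
mortality,Urate,0.004
stm,Glutamate,-1.327
stm,Ornithine,1.064
stm,Tryptophan,-0.650
stm,Cystine,-0.278
stm,Fumarate,1.221
stm,Acetylcarnitine,0.845
stm,Eicosapentanoate,-0.102
stm,Histidine,1.296
stm,Linoleate,-0.896
stm,Kynurenine,0.865
stm,Myristoylcarnitine,0.606
stm,Octanylcarnitine,1.409
stm,Sphingosine 1 phosphate,-1.729
stm,Trimethyl N oxide,0.144
stm,Urate,0.548
pecam,Glycine,-1.728
pecam,Valine,-1.222
pecam,Isoleucine,-1.083
pecam,Threonine,3.463
pecam,Glutamate,0.978
pecam,Phenylalanine,-0.104
pecam,Tryptophan,-0.983
pecam,Aspartate,0.887
pecam,Pyruvate,-0.435
pecam,Succinate,-0.430
pecam,Arachidonate,0.671
pecam,Arginine,0.732
pecam,Docosahexanoate,-0.897
pecam,Gamma Linolenicate A,-0.605
pecam,Glucose,-0.610
pecam,Glutamine,0.206
pecam,Histidine,1.869
pecam,Linolenate,-0.212
pecam,Myristoylcarnitine,-0.379
pecam,Propionylcarnitine,0.107
pecam,Sphingosine 1 phosphate,-0.865
pecam,Trimethyl N oxide,0.363
pecam,Urate,1.832
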