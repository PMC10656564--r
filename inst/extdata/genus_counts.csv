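genus,n_dead,n_trees,period_years
All,180765,1050960,4
Pinus,66341,312930,4
Abies,78069,375333,4
Quercus,13906,128764,4
Cedrus,23393,233933,4
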