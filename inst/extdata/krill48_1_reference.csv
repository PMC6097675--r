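cfg,n_pars,median_iterations,pct_best,nll,max_gradient,delta_aic,delta_bic,coda_pass
I,48,1,100,17247,3.51e-05,11616,11474,TRUE
II,49,1,100,14223,2.16e-05,5570,5431,TRUE
III,49,1,100,16528,4.19e-05,10180,10041,TRUE
IV,49,1,100,17070,3.02e-05,11264,11125,TRUE
V,49,1,100,17106,2.50e-05,11336,11197,TRUE
VI,51,1,80,13604,1.06e-06,4336,4203,TRUE
VII,54,1,100,16368,3.14e-05,9870,9746,TRUE
VIII,63,13,5,13446,3.67e-03,4044,3946,FALSE
IX,90,1,30,13692,3.42e-05,4590,4572,TRUE
X,91,1,95,12054,7.05e-06,1316,1301,TRUE
XI,91,1,100,11766,1.91e-05,740,725,TRUE
XII,92,1,95,11766,2.72e-05,742,730,FALSE
XIII,93,1,95,11643,9.36e-06,498,489,TRUE
XIV,94,1,55,11487,1.52e-05,188,182,TRUE
XV,96,1,15,11417,6.66e-05,52,52,TRUE
XVI,96,1,27,11391,3.77e-05,0,0,TRUE
XVII,104,3,30,11384,4.52e-05,2,26,FALSE
XVIII,104,19,40,12342,4.10e-05,1918,1942,FALSE
XIX,105,8,10,11540,7.06e-02,316,343,FALSE
XX,106,2,25,11386,5.84e-05,10,40,FALSE
XXI,107,2,35,11383,2.25e-05,6,39,FALSE
XXII,107,2,15,11383,1.92e-05,6,39,FALSE
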