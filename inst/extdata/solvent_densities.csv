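name,density_g_per_ml
water,0.998
methanol,0.791
ethanol,0.789
acetonitrile,0.786
toluene,0.867
acetone,0.790
acetic acid,1.049
chloroform,1.489
dichloromethane,1.325
hexane,0.655
dimethylformamide,0.944
dimethyl sulfoxide,1.100
pyridine,0.982
tetrahydrofuran,0.889
diethyl ether,0.713
ethyl acetate,0.902
isopropanol,0.786
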