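wavelength_nm,eps_hbo,eps_hb,eps_ccodiff,mua_water
690,6.355135e-04,4.724813e-03,2.100000e-03,4.9000e-03
784,1.693782e-03,2.317782e-03,3.550000e-03,2.2800e-02
800,1.878909e-03,1.753925e-03,4.200000e-03,2.0400e-02
818,2.085221e-03,1.608125e-03,4.750000e-03,2.2800e-02
830,2.242718e-03,1.595784e-03,4.950000e-03,2.8000e-02
835,2.297980e-03,1.595001e-03,4.920000e-03,3.0500e-02
851,2.442582e-03,1.592007e-03,4.700000e-03,4.1000e-02
868,2.552185e-03,1.603060e-03,4.300000e-03,4.8000e-02
881,2.662709e-03,1.676282e-03,4.000000e-03,5.5300e-02
894,2.730866e-03,1.726709e-03,3.650000e-03,6.2500e-02
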