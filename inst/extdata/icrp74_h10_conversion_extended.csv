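# Neutron fluence to ambient dose equivalent H*(10) conversion coefficients,
# pSv cm^2 per neutron, ICRP Publication 74 tabulation (thermal to 201 MeV).
# Rows above 201 MeV are a SYNTHETIC smooth extension to the 240 MeV
# transport cutoff added for this package; edit this file to substitute a
# preferred high-energy data source.
energy_MeV,h10_pSv_cm2
1.0e-9,6.60
1.0e-8,9.00
2.53e-8,10.6
1.0e-7,12.9
2.0e-7,13.5
5.0e-7,13.6
1.0e-6,13.3
2.0e-6,12.9
5.0e-6,12.0
1.0e-5,11.3
2.0e-5,10.6
5.0e-5,9.90
1.0e-4,9.40
2.0e-4,8.90
5.0e-4,8.30
1.0e-3,7.90
2.0e-3,7.70
5.0e-3,8.00
1.0e-2,10.5
2.0e-2,16.6
3.0e-2,23.7
5.0e-2,41.1
7.0e-2,60.0
1.0e-1,88.0
1.5e-1,132
2.0e-1,170
3.0e-1,233
5.0e-1,322
7.0e-1,375
9.0e-1,400
1.0,416
1.2,425
2.0,420
3.0,412
4.0,408
5.0,405
6.0,400
7.0,405
8.0,409
9.0,420
10.0,440
12.0,480
14.0,520
15.0,540
16.0,555
18.0,570
20.0,600
30.0,515
50.0,400
75.0,330
100.0,285
125.0,260
150.0,245
175.0,250
201.0,260
# --- synthetic extension beyond the ICRP 74 tabulation ---
220.0,265
240.0,270
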