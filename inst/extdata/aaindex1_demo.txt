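H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500
     3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200
//
H GRAR740102
D Polarity (Grantham, 1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     8.100  10.500  11.600  13.000   5.500  10.500  12.300   9.000  10.400   5.200
     4.900  11.300   5.700   5.200   8.000   9.200   8.600   5.400   6.200   5.900
//
H FAUJ880103
D Normalized van der Waals volume (Fauchere et al., 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.000   6.130   2.950   2.780   2.430   3.950   3.780   0.000   4.660   4.000
     4.000   4.770   4.430   5.890   2.720   1.600   2.600   8.080   6.470   3.000
//
H ZIMJ680104
D Isoelectric point (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     6.000  10.760   5.410   2.770   5.050   5.650   3.220   5.970   7.590   6.020
     5.980   9.740   5.740   5.480   6.300   5.680   5.660   5.890   5.660   5.960
//
H CHOC760101
D Residue accessible surface area in tripeptide (Chothia, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   115.000 225.000 160.000 150.000 135.000 180.000 190.000  75.000 195.000 175.000
   170.000 200.000 185.000 210.000 145.000 115.000 140.000 255.000 230.000 155.000
//
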