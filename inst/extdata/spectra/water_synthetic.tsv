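# Synthetic NIR absorption table: water (pure, volume fraction 1).
# Smooth approximation of the standard literature shape: very low absorption below 900 nm
# with the 740 nm overtone bump, rising steeply to the ~970 nm band; values in 1/cm.
# wavelength_nm	mu_a_per_cm
670	0.004
680	0.004
690	0.005
700	0.006
710	0.011
720	0.016
730	0.022
740	0.026
750	0.026
760	0.025
770	0.024
780	0.023
790	0.024
800	0.022
810	0.028
820	0.034
830	0.036
840	0.040
850	0.043
860	0.050
870	0.056
880	0.060
890	0.064
900	0.068
910	0.080
920	0.110
930	0.140
940	0.270
950	0.390
960	0.430
970	0.450
980	0.430
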