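# Synthetic NIR absorption table: lipid (pure fat, volume fraction 1).
# Smooth approximation of the standard literature shape: low absorption through 680-880 nm,
# a weak 760 nm overtone, and the characteristic strong peak at 930 nm; values in 1/cm.
# wavelength_nm	mu_a_per_cm
670	0.010
680	0.009
690	0.008
700	0.008
710	0.009
720	0.012
730	0.020
740	0.028
750	0.030
760	0.032
770	0.030
780	0.028
790	0.030
800	0.035
810	0.040
820	0.050
830	0.070
840	0.080
850	0.075
860	0.070
870	0.080
880	0.110
890	0.180
900	0.330
910	0.620
920	1.000
930	1.150
940	0.850
950	0.480
960	0.360
970	0.330
980	0.330
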