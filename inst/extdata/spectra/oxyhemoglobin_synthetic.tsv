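# Synthetic NIR absorption table: oxyhemoglobin, whole blood at 150 g Hb/L, fully oxygenated.
# Smooth approximation of the standard literature shape (gentle monotone rise from 700 nm
# to a broad plateau near 900-940 nm); values in 1/cm.
# wavelength_nm	mu_a_per_cm
670	3.10
680	2.60
690	2.10
700	1.80
710	1.70
720	1.70
730	1.80
740	2.00
750	2.20
760	2.40
770	2.70
780	3.00
790	3.40
800	3.80
810	4.10
820	4.40
830	4.70
840	4.90
850	5.20
860	5.40
870	5.60
880	5.70
890	5.80
900	5.90
910	6.00
920	6.10
930	6.20
940	6.20
950	6.10
960	6.00
970	5.90
980	5.80
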