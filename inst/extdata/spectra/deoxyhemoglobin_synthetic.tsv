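# Synthetic NIR absorption table: deoxyhemoglobin, whole blood at 150 g Hb/L, fully deoxygenated.
# Smooth approximation of the standard literature shape (steep decline from 680 nm with the
# characteristic 760 nm shoulder, then a slow decay); values in 1/cm.
# wavelength_nm	mu_a_per_cm
670	15.50
680	13.50
690	11.50
700	9.60
710	8.40
720	7.60
730	7.10
740	7.00
750	7.30
760	7.50
770	6.80
780	5.80
790	4.90
800	4.20
810	3.80
820	3.50
830	3.30
840	3.20
850	3.10
860	3.00
870	3.00
880	2.90
890	2.90
900	2.90
910	2.80
920	2.80
930	2.80
940	2.70
950	2.70
960	2.60
970	2.60
980	2.50
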