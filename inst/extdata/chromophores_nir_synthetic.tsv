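# Synthetic NIR chromophore compilation (see data-raw/make_chromophore_table.R).
# Smooth spectra interpolated through landmark anchor values from the standard
# tissue-optics literature; a constructed stand-in, not a verbatim published table.
# Columns: wavelength_nm, mu_a_hbo2, mu_a_hb (whole blood at 150 g/L hemoglobin,
# cm^-1), mu_a_water (pure water, cm^-1), mu_a_melanin (melanosome interior, cm^-1).
wavelength_nm	mu_a_hbo2	mu_a_hb	mu_a_water	mu_a_melanin
650	1.970584	20.080684	0.0034	276.382436
655	1.834294	18.647574	0.003639	269.109604
660	1.713552	17.280098	0.003883	262.081295
665	1.620648	16.030064	0.004136	255.287527
670	1.554853	14.893988	0.004404	248.718797
675	1.512181	13.854561	0.00469	242.366054
680	1.488648	12.894477	0.005	236.220674
685	1.480997	11.998069	0.00533	230.274439
690	1.488894	11.15625	0.005639	224.51951
695	1.512732	10.361575	0.005878	218.948413
700	1.552906	9.606599	0.006	213.554016
705	1.609508	8.89144	0.006049	208.329511
710	1.681423	8.246468	0.006452	203.2684
715	1.766977	7.682328	0.007729	198.364474
720	1.863487	7.10053	0.0104	193.611805
725	1.969361	6.440321	0.014698	189.004724
730	2.088391	5.901044	0.019703	184.537812
735	2.22594	5.71372	0.024206	180.20589
740	2.388263	5.976012	0.027	176.003999
745	2.576921	6.679344	0.027373	171.927399
750	2.773812	7.523563	0.0266	167.971548
755	2.960631	8.154644	0.026078	164.132101
760	3.137942	8.294661	0.0257	160.404896
765	3.31046	7.804671	0.02508	156.785945
770	3.480652	7.025562	0.024232	153.271426
775	3.647956	6.332317	0.023268	149.857677
780	3.801943	5.756463	0.0223	146.541187
785	3.936129	5.253637	0.02144	143.318586
790	4.069685	4.819364	0.020796	140.186645
795	4.219734	4.458932	0.02048	137.142264
800	4.369557	4.176782	0.0206	134.182465
805	4.501322	3.974043	0.021204	131.304393
810	4.62659	3.839427	0.022094	128.505305
815	4.760741	3.75845	0.023012	125.782564
820	4.905042	3.716265	0.0237	123.133639
825	5.0562	3.699009	0.02408	120.556097
830	5.20681	3.697126	0.024802	118.047599
835	5.34844	3.702135	0.026698	115.605897
840	5.472656	3.705556	0.0306	113.228826
845	5.574814	3.702219	0.036784	110.914308
850	5.66543	3.700201	0.0433	108.66034
855	5.756084	3.708729	0.04814	106.464996
860	5.847462	3.72841	0.051274	104.326422
865	5.937529	3.757691	0.05317	102.242831
870	6.024247	3.795021	0.054295	100.212506
875	6.105582	3.838848	0.055116	98.233789
880	6.179496	3.88762	0.0561	96.305086
885	6.244811	3.939463	0.057665	94.424858
890	6.303778	3.991204	0.060036	92.591623
895	6.359508	4.039347	0.063389	90.803954
900	6.415109	4.080395	0.0679	89.060471
905	6.471943	4.111994	0.073917	87.359847
910	6.524371	4.136356	0.082471	85.7008
915	6.565007	4.156835	0.094764	84.082093
920	6.586464	4.176782	0.112	82.502533
925	6.583982	4.198512	0.135577	80.960968
930	6.563298	4.220176	0.167681	79.456286
935	6.532778	4.238885	0.210695	77.987413
940	6.500787	4.25175	0.267	76.553313
945	6.473362	4.257641	0.333852	75.152984
950	6.447238	4.26246	0.388	73.785458
955	6.41763	4.270574	0.410482	72.4498
960	6.38298	4.27317	0.42	71.145106
965	6.342547	4.261115	0.436846	69.870503
970	6.295622	4.237193	0.45	68.625147
975	6.241505	4.207162	0.445633	67.40822
980	6.179496	4.176782	0.43	66.218933
985	6.109369	4.150628	0.412494	65.056522
990	6.032798	4.128532	0.394993	63.920247
995	5.95193	4.109142	0.377496	62.809394
1000	5.868915	4.091105	0.36	61.723269
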