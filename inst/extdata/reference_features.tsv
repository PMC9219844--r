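metabolite	pathway	fraction	fold_change	p_value	mz	rt	adduct	theoretical_mz	ppm	verified	ambiguous
alpha-linolenate	eicosapentaenoate biosynthesis II	pellet	32.2	2.2e-07	261.2201	1.4	M-H2O[1+]	261.221291	-4.56	TRUE	FALSE
alpha-linolenate	eicosapentaenoate biosynthesis II	pellet	42.5	2e-06	279.2305	1.39	M+H[1+]	279.231856	-4.857	TRUE	TRUE
HPETE	leukotriene biosynthesis	pellet	2.5	6e-06	169.1215	0.85	M+2H[2+]	169.122306	-4.764	TRUE	FALSE
S-3-methyl-2-oxopentanoate	isoleucine degradation	pellet	11.1	4.4e-07	113.0591	0.75	M-H2O[1+]	113.059705	-5.353	TRUE	FALSE
2-trans-hexadecenal	sphingosine metabolism	pellet	15.8	1.2e-05	261.2201	0.87	M+Na[1+]	261.218884	4.657	TRUE	TRUE
2-trans-hexadecenal	sphingosine metabolism	pellet	32.2	2.2e-07	261.2201	1.4	M+Na[1+]	261.218884	4.657	TRUE	TRUE
3-ureido-isobutyrate	thymine degradation	pellet	18.4	3.6e-05	169.0579	1.06	M+Na[1+]	169.05836	-2.722	TRUE	FALSE
4-hydroxy-2-nonenal-glutathione conjugate	4-hydroxy-2-nonenal detoxification	pellet	15	1.2e-06	465.2138	5.09	M+H[1+]	464.206112	2170.777	FALSE	FALSE
glutathione disulfide	glutaredoxin ascorbate recycling	pellet	236.6	1.6e-05	308.0897	0.52	M+2H[2+]	307.083257	3277.426	FALSE	FALSE
hypoxanthine	purine degradation	pellet	42.3	7.7e-05	119.0346	0.52	M-H2O[1+]	119.035222	-5.223	TRUE	FALSE
hypoxanthine	purine degradation	pellet	583.7	7.7e-06	137.0451	0.53	M+H[1+]	137.045787	-5.011	TRUE	FALSE
laurate	palmitate biosynthesis	pellet	4.9	3e-05	223.1667	0.79	M+Na[1+]	223.166848	-0.663	TRUE	FALSE
methylhistamine	histamine degradation	pellet	3.9	3.4e-07	144.1374	0.77	M+NH3[1+]	143.12912	7044.546	FALSE	FALSE
N-acetylputrescine	putrescine degradation III	pellet	3	1.8e-06	170.081	0.73	M+K[1+]	169.073771	5957.334	FALSE	TRUE
oleate	oleate biosynthesis	pellet	2	5.5e-05	300.2884	3.19	M+NH3[1+]	300.289703	-4.34	TRUE	FALSE
oleate	oleate biosynthesis	pellet	10.2	4e-05	153.1264	1.37	M+H+Na[2+]	153.126187	1.39	TRUE	FALSE
palmitate	aldehydesphingosine and sphingosine-1-phosphate metabolism	pellet	43.8	8e-07	263.2354	1.34	M+Na[1+]	279.229448	-57279.232	FALSE	FALSE
palmitate	palmitate biosynthesis-stearate biosynthesis	pellet	42.5	2e-06	279.2305	1.39	M+Na[1+]	279.229448	3.767	TRUE	FALSE
pyridoxine	pyridoxal 5'-phosphate salvage	pellet	3	1.8e-06	170.081	0.73	M+H[1+]	170.081169	-0.995	TRUE	FALSE
S-methyl-5'-thioadenosine	wyosine biosynthesis	pellet	43.4	7.2e-05	298.0963	0.54	M+H[1+]	298.096837	-1.8	TRUE	FALSE
urocanate	histidine degradation	pellet	3.7	2e-07	156.076	0.5	M+NH3[1+]	156.07675	-4.808	TRUE	FALSE
1-pyrroline-3-hydroxy-5-carboxylate	4-hydroxyproline degradation	media	-3.7	1.3e-05	130.0493	0.5	M+H[1+]	130.049869	-4.376	TRUE	TRUE
S-dihydroorotate	UMP biosynthesis	media	-20.5	1.8e-05	176.066	1.21	M+NH3[1+]	176.06658	-3.292	TRUE	FALSE
3-4-dihydroxy-5-all-trans-decaprenylbenzoate	ubiquinol-10 biosynthesis	media	-3	1.9e-05	835.659	8.84	M+H[1+]	835.659887	-1.062	TRUE	FALSE
3-ureido-isobutyrate	thymine degradation	media	-3.7	1.3e-05	130.0493	0.5	M-NH3[1+]	130.049868	-4.369	TRUE	FALSE
5S-hydroperoxy-18R-hydroxy-eicosapentaenoate	resolvin E biosynthesis	media	-138.8	4e-05	333.2044	1.57	M-H2O[1+]	333.206035	-4.907	TRUE	TRUE
all-trans-retinoate	retinoate biosynthesis	media	-4.2	2.5e-08	283.2043	2.22	M-H2O[1+]	283.205641	-4.736	TRUE	FALSE
all-trans-retinoate	retinoate biosynthesis	media	-33.9	1.2e-05	323.1968	1.11	M+Na[1+]	323.198148	-4.171	TRUE	FALSE
all-trans-retinoate	retinoate biosynthesis	media	-141.3	4.2e-06	323.1966	1.53	M+Na[1+]	323.198148	-4.79	TRUE	FALSE
biliverdin-IX	heme degradation	media	-3281.8	5.3e-06	600.2797	1.28	M+NH3[1+]	600.281658	-3.262	TRUE	FALSE
codeine	morphine biosynthesis	media	-3.7	8.2e-05	318.1929	0.84	M+NH3[1+]	317.185967	3174.584	FALSE	TRUE
D-sorbitol	sorbitol degradation I	media	-5	3.1e-05	205.0675	1.16	M+Na[1+]	205.068256	-3.687	TRUE	FALSE
N-formylkynurenine	tryptophan degradation	media	-4.3	5e-05	255.1223	0.86	M+NH3[1+]	254.11353	3969.762	FALSE	FALSE
resolvin E1	resolvin E biosynthesis	media	-138.8	4e-05	333.2044	1.57	M-H2O[1+]	333.206035	-4.907	TRUE	TRUE
resolvin E2	resolvin E biosynthesis	media	-8.8	2.6e-05	317.2101	0.88	M-H2O[1+]	317.21112	-3.217	TRUE	FALSE
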