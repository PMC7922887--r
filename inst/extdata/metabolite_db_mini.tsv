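name	hmdb_id	formula	monoisotopic_mass	pathways
Ascorbic acid	HMDB0000044	C6H8O6	176.0321	Glutathione metabolism
Cyclic AMP	HMDB0000058	C10H12N5O6P	329.0525	Purine metabolism
Creatine	HMDB0000064	C4H9N3O2	131.0695	Glycine, serine and threonine metabolism;Arginine and proline metabolism
Pipecolic acid	HMDB0000070	C6H11NO2	129.079	Lysine degradation
Guanine	HMDB0000132	C5H5N5O	151.0494	Purine metabolism
Glycocholic acid	HMDB0000138	C26H43NO6	465.309	Primary bile acid biosynthesis
Hypoxanthine	HMDB0000157	C5H4N4O	136.0385	Purine metabolism
L-Tyrosine	HMDB0000158	C9H11NO3	181.0739	Tyrosine metabolism;Phenylalanine, tyrosine and tryptophan biosynthesis;Phenylalanine metabolism;Aminoacyl-tRNA biosynthesis
L-Phenylalanine	HMDB0000159	C9H11NO2	165.079	Phenylalanine metabolism;Phenylalanine, tyrosine and tryptophan biosynthesis;Aminoacyl-tRNA biosynthesis
L-Alanine	HMDB0000161	C3H7NO2	89.0477	Alanine, aspartate and glutamate metabolism;Aminoacyl-tRNA biosynthesis
L-Proline	HMDB0000162	C5H9NO2	115.0633	Arginine and proline metabolism;Aminoacyl-tRNA biosynthesis
L-Histidine	HMDB0000177	C6H9N3O2	155.0695	Histidine metabolism;Nitrogen metabolism;Aminoacyl-tRNA biosynthesis
L-Lysine	HMDB0000182	C6H14N2O2	146.1055	Lysine degradation;Aminoacyl-tRNA biosynthesis
L-Cystine	HMDB0000192	C6H12N2O4S2	240.0238	Cysteine and methionine metabolism
Phenylpyruvic acid	HMDB0000205	C9H8O3	164.0473	Phenylalanine metabolism;Phenylalanine, tyrosine and tryptophan biosynthesis
N6-Acetyl-L-lysine	HMDB0000206	C8H16N2O3	188.1161	Lysine degradation
Nicotinamide ribotide	HMDB0000229	C11H15N2O8P	334.0566	
Taurine	HMDB0000251	C2H7NO3S	125.0147	Taurine and hypotaurine metabolism;Nitrogen metabolism;Primary bile acid biosynthesis
Xanthosine	HMDB0000299	C10H12N4O6	284.0757	Purine metabolism
Aminoadipic acid	HMDB0000510	C6H11NO4	161.0688	Lysine degradation
3-Methylglutarylcarnitine	HMDB0000552	C13H23NO6	289.1525	
L-Cysteine	HMDB0000574	C3H7NO2S	121.0197	Cysteine and methionine metabolism;Glutathione metabolism;Taurine and hypotaurine metabolism;Aminoacyl-tRNA biosynthesis
Erythronic acid	HMDB0000613	C4H8O5	136.0372	
L-Homocystine	HMDB0000676	C8H16N2O4S2	268.0551	Cysteine and methionine metabolism
Harderoporphyrin	HMDB0000683	C35H36N4O5	592.2686	
L-Kynurenine	HMDB0000684	C10H12N2O3	208.0848	Tryptophan metabolism
L-Leucine	HMDB0000687	C6H13NO2	131.0946	Valine, leucine and isoleucine degradation;Aminoacyl-tRNA biosynthesis
Isovalerylcarnitine	HMDB0000688	C12H23NO4	245.1627	Valine, leucine and isoleucine degradation
Hydroxyproline	HMDB0000725	C5H9NO3	131.0582	Arginine and proline metabolism
Indoleacrylic acid	HMDB0000734	C11H9NO2	187.0633	Tryptophan metabolism
5-Hydroxyindoleacetic acid	HMDB0000763	C10H9NO3	191.0582	Tryptophan metabolism
Oxypurinol	HMDB0000786	C5H4N4O2	152.0334	Purine metabolism
Succinyladenosine	HMDB0000912	C14H17N5O8	383.1077	Purine metabolism
Valerylglycine	HMDB0000927	C7H13NO3	159.0895	
L-Tryptophan	HMDB0000929	C11H12N2O2	204.0899	Tryptophan metabolism;Phenylalanine, tyrosine and tryptophan biosynthesis;Aminoacyl-tRNA biosynthesis
S-Adenosylhomocysteine	HMDB0000939	C14H20N4O5S	356.1154	Cysteine and methionine metabolism
N-Acetylaspartylglutamic acid	HMDB0001067	C11H16N2O8	304.0907	Alanine, aspartate and glutamate metabolism
6,8-Dihydroxypurine	HMDB0001182	C5H4N4O2	152.0334	Purine metabolism
N-Acetylserotonin	HMDB0001238	C12H14N2O2	218.1055	Tryptophan metabolism
N-Acetylarylamine	HMDB0001250	C8H9NO	135.0684	
1-Methylguanosine	HMDB0001563	C11H15N5O5	297.1073	
Acetaminophen	HMDB0001859	C8H9NO2	151.0633	
Benzoic acid	HMDB0001870	C7H6O2	122.0368	Phenylalanine metabolism
Omeprazole	HMDB0001913	C17H19N3O3S	345.1147	
2-Pyrrolidinone	HMDB0002039	C4H7NO	85.0528	
Carnosol	HMDB0002121	C20H26O4	330.1831	
Phenylpropiolic acid	HMDB0002359	C9H6O2	146.0368	Phenylalanine metabolism
Shikimic acid	HMDB0003070	C7H10O5	174.0528	Phenylalanine, tyrosine and tryptophan biosynthesis
Berberine	HMDB0003409	C20H18NO4	336.1236	
L-Gulonolactone	HMDB0003466	C6H10O6	178.0477	
19-Hydroxyandrost-4-ene-3,17-dione	HMDB0003955	C19H26O3	302.1882	
Dopamine 4-sulfate	HMDB0004148	C8H11NO5S	233.0358	Tyrosine metabolism
3-Methyluridine	HMDB0004813	C10H14N2O6	258.0852	
Sumatriptan	HMDB0005037	C14H21N3O2S	295.1354	
DG(20:1(11Z)/20:4(5Z,8Z,11Z,14Z)/0:0)[iso2]	HMDB0005233	C43H74O5	670.5536	
Ophthalmic acid	HMDB0005765	C11H19N3O6	289.1274	Glutathione metabolism
2-Methylguanosine	HMDB0005862	C11H15N5O5	297.1073	
Malondialdehyde	HMDB0006112	C3H4O2	72.0211	
Glycine	HMDB0000123	C2H5NO2	75.032	Glutathione metabolism;Glycine, serine and threonine metabolism;Nitrogen metabolism;Primary bile acid biosynthesis;Aminoacyl-tRNA biosynthesis
Asparagine	HMDB0000168	C4H8N2O3	132.0535	Alanine, aspartate and glutamate metabolism;Aminoacyl-tRNA biosynthesis
Serine	HMDB0000187	C3H7NO3	105.0426	Glycine, serine and threonine metabolism;Cysteine and methionine metabolism;Aminoacyl-tRNA biosynthesis
Ornithine	HMDB0000214	C5H12N2O2	132.0899	Arginine and proline metabolism;Glutathione metabolism
Serotonin	HMDB0000259	C10H12N2O	176.095	Tryptophan metabolism
Sarcosine	HMDB0000271	C3H7NO2	89.0477	Glycine, serine and threonine metabolism
Tryptamine	HMDB0000303	C10H12N2	160.1	Tryptophan metabolism
Tyramine	HMDB0000306	C8H11NO	137.0841	Tyrosine metabolism
Methionine	HMDB0000696	C5H11NO2S	149.051	Cysteine and methionine metabolism;Aminoacyl-tRNA biosynthesis
Kynurenic acid	HMDB0000715	C10H7NO3	189.0426	Tryptophan metabolism
Xanthurenic acid	HMDB0000881	C10H7NO4	205.0375	Tryptophan metabolism
Valine	HMDB0000883	C5H11NO2	117.079	Valine, leucine and isoleucine degradation;Aminoacyl-tRNA biosynthesis
Citrulline	HMDB0000904	C6H13N3O3	175.0957	Arginine and proline metabolism
Spermidine	HMDB0001257	C7H19N3	145.1579	Arginine and proline metabolism;Glutathione metabolism
N1-Acetylspermidine	HMDB0001276	C9H21N3O	187.1685	Arginine and proline metabolism
ADMA	HMDB0001539	C8H18N4O2	202.143	Arginine and proline metabolism
Cadaverine	HMDB0002322	C5H14N2	102.1157	Lysine degradation
Glutathione	HMDB0000125	C10H17N3O6S	307.0838	Glutathione metabolism;Cysteine and methionine metabolism
Glutathione disulfide	HMDB0003337	C20H32N6O12S2	612.152	Glutathione metabolism
5-Oxoproline	HMDB0000267	C5H7NO3	129.0426	Glutathione metabolism
gamma-Glutamylcysteine	HMDB0001049	C8H14N2O5S	250.0623	Glutathione metabolism
L-Glutamate	HMDB0000148	C5H9NO4	147.0532	Glutathione metabolism;Alanine, aspartate and glutamate metabolism;Nitrogen metabolism;Arginine and proline metabolism;Aminoacyl-tRNA biosynthesis
L-Glutamine	HMDB0000641	C5H10N2O3	146.0691	Alanine, aspartate and glutamate metabolism;Nitrogen metabolism;Purine metabolism;Aminoacyl-tRNA biosynthesis
Hypotaurine	HMDB0000965	C2H7NO2S	109.0197	Taurine and hypotaurine metabolism
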