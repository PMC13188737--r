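gene	pathway
K00001	amino_acid_biosynthesis
K00002	amino_acid_biosynthesis
K00003	amino_acid_biosynthesis
K00004	amino_acid_biosynthesis
K00005	amino_acid_biosynthesis
K00006	amino_acid_biosynthesis
K00007	amino_acid_biosynthesis
K00008	amino_acid_biosynthesis
K00009	amino_acid_biosynthesis
K00010	amino_acid_biosynthesis
K00011	lipid_biosynthesis
K00012	lipid_biosynthesis
K00013	lipid_biosynthesis
K00014	lipid_biosynthesis
K00015	lipid_biosynthesis
K00016	lipid_biosynthesis
K00017	lipid_biosynthesis
K00018	lipid_biosynthesis
K00019	lipid_biosynthesis
K00020	lipid_biosynthesis
K00021	nucleotide_biosynthesis
K00022	nucleotide_biosynthesis
K00023	nucleotide_biosynthesis
K00024	nucleotide_biosynthesis
K00025	nucleotide_biosynthesis
K00026	nucleotide_biosynthesis
K00027	nucleotide_biosynthesis
K00028	nucleotide_biosynthesis
K00029	nucleotide_biosynthesis
K00030	nucleotide_biosynthesis
K00031	peptidoglycan_biosynthesis
K00032	peptidoglycan_biosynthesis
K00033	peptidoglycan_biosynthesis
K00034	peptidoglycan_biosynthesis
K00035	peptidoglycan_biosynthesis
K00036	peptidoglycan_biosynthesis
K00037	peptidoglycan_biosynthesis
K00038	peptidoglycan_biosynthesis
K00039	peptidoglycan_biosynthesis
K00040	peptidoglycan_biosynthesis
K00041	teichoic_acid_biosynthesis
K00042	teichoic_acid_biosynthesis
K00043	teichoic_acid_biosynthesis
K00044	teichoic_acid_biosynthesis
K00045	teichoic_acid_biosynthesis
K00046	teichoic_acid_biosynthesis
K00047	teichoic_acid_biosynthesis
K00048	teichoic_acid_biosynthesis
K00049	teichoic_acid_biosynthesis
K00050	teichoic_acid_biosynthesis
K00051	eps_biosynthesis
K00052	eps_biosynthesis
K00053	eps_biosynthesis
K00054	eps_biosynthesis
K00055	eps_biosynthesis
K00056	eps_biosynthesis
K00057	eps_biosynthesis
K00058	eps_biosynthesis
K00059	eps_biosynthesis
K00060	eps_biosynthesis
K00061	amino_acid_degradation
K00062	amino_acid_degradation
K00063	amino_acid_degradation
K00064	amino_acid_degradation
K00065	amino_acid_degradation
K00066	amino_acid_degradation
K00067	amino_acid_degradation
K00068	amino_acid_degradation
K00069	amino_acid_degradation
K00070	amino_acid_degradation
K00071	lipid_degradation
K00072	lipid_degradation
K00073	lipid_degradation
K00074	lipid_degradation
K00075	lipid_degradation
K00076	lipid_degradation
K00077	lipid_degradation
K00078	lipid_degradation
K00079	lipid_degradation
K00080	lipid_degradation
K00081	nucleotide_degradation
K00082	nucleotide_degradation
K00083	nucleotide_degradation
K00084	nucleotide_degradation
K00085	nucleotide_degradation
K00086	nucleotide_degradation
K00087	nucleotide_degradation
K00088	nucleotide_degradation
K00089	nucleotide_degradation
K00090	nucleotide_degradation
K00091	aromatic_degradation
K00092	aromatic_degradation
K00093	aromatic_degradation
K00094	aromatic_degradation
K00095	aromatic_degradation
K00096	aromatic_degradation
K00097	aromatic_degradation
K00098	aromatic_degradation
K00099	aromatic_degradation
K00100	aromatic_degradation
K00101	c_ring_degradation
K00102	c_ring_degradation
K00103	c_ring_degradation
K00104	c_ring_degradation
K00105	c_ring_degradation
K00106	c_ring_degradation
K00107	c_ring_degradation
K00108	c_ring_degradation
K00109	c_ring_degradation
K00110	c_ring_degradation
K00111	central_c_metabolism
K00112	central_c_metabolism
K00113	central_c_metabolism
K00114	central_c_metabolism
K00115	central_c_metabolism
K00116	central_c_metabolism
K00117	central_c_metabolism
K00118	central_c_metabolism
K00119	central_c_metabolism
K00120	central_c_metabolism
K00121	pyruvate_oxidation
K00122	pyruvate_oxidation
K00123	pyruvate_oxidation
K00124	pyruvate_oxidation
K00125	pyruvate_oxidation
K00126	pyruvate_oxidation
K00127	pyruvate_oxidation
K00128	pyruvate_oxidation
K00129	pyruvate_oxidation
K00130	pyruvate_oxidation
K00131	electron_transport_chain
K00132	electron_transport_chain
K00133	electron_transport_chain
K00134	electron_transport_chain
K00135	electron_transport_chain
K00136	electron_transport_chain
K00137	electron_transport_chain
K00138	electron_transport_chain
K00139	electron_transport_chain
K00140	electron_transport_chain
K00141	atpase
K00142	atpase
K00143	atpase
K00144	atpase
K00145	atpase
K00146	atpase
K00147	atpase
K00148	atpase
K00149	atpase
K00150	atpase
K00151	fermentation
K00152	fermentation
K00153	fermentation
K00154	fermentation
K00155	fermentation
K00156	fermentation
K00157	fermentation
K00158	fermentation
K00159	fermentation
K00160	fermentation
K00161	pomp
K00162	pomp
K00163	pomp
K00164	pomp
K00165	pomp
K00166	pomp
K00167	pomp
K00168	pomp
K00169	pomp
K00170	pomp
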