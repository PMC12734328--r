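osmolyte_metabolism	synthetic term: osmolyte biosynthesis genes	g00001	g00002	g00003	g00004	g00005	g00006	g00007	g00008
cell_wall_remodeling	synthetic term: chitin and glucan remodeling	g00026	g00027	g00028	g00029	g00030	g00031	g00032	g00033	g00034	g00035
ros_detoxification	synthetic term: catalases, SODs, GSTs	g00051	g00052	g00053	g00054	g00055	g00056	g00057	g00058	g00059
glycolysis	synthetic term: glycolytic enzymes	g00076	g00077	g00078	g00079	g00080	g00081	g00082
membrane_transport	synthetic term: MFS and ion transporters	g00101	g00102	g00103	g00104	g00105	g00106	g00107	g00108	g00109	g00110	g00111	g00112
ribosome_biogenesis	synthetic term: ribosomal proteins	g00151	g00152	g00153	g00154	g00155	g00156	g00157	g00158	g00159	g00160
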