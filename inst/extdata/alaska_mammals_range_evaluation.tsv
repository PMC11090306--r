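order	family	species	common_name	n_records	extralimital_total	extralimital_recent	akgap_sensitivity	iucn_sensitivity	akgap_hu_occupancy	range_area_km2
Artiodactyla	Bovidae	Oreamnos americanus	Mountain Goat	1747	0	0	n/a	n/a	n/a	n/a
Artiodactyla	Bovidae	Ovis dalli	Dall's Sheep	795	0	0	n/a	n/a	n/a	n/a
Artiodactyla	Cervidae	Alces alces	Moose	3032	0	0	n/a	n/a	n/a	n/a
Artiodactyla	Cervidae	Odocoileus hemionus	Mule Deer	444	0	0	n/a	n/a	n/a	n/a
Artiodactyla	Cervidae	Rangifer tarandus	Caribou	4429	0	0	n/a	n/a	n/a	n/a
Carnivora	Canidae	Canis latrans	Coyote	168	68	4	100.0	99.4	19.5	489481
Carnivora	Canidae	Canis lupus	Gray Wolf	2637	0	0	n/a	n/a	n/a	n/a
Carnivora	Canidae	Vulpes vulpes	Red Fox	1425	92	30	97.1	94.7	74.8	1388868
Carnivora	Felidae	Lynx canadensis	Canadian Lynx	2210	26	10	99.4	99.6	58.4	1066301
Carnivora	Felidae	Puma concolor	Mountain Lion	2	0	0	n/a	n/a	n/a	n/a
Carnivora	Mustelidae	Gulo gulo	Wolverine	915	0	0	n/a	n/a	n/a	n/a
Carnivora	Mustelidae	Lontra canadensis	North American River Otter	352	77	21	98.0	75.3	44.4	1243695
Carnivora	Mustelidae	Martes americana	American Marten	7195	0	0	n/a	n/a	n/a	n/a
Carnivora	Mustelidae	Martes caurina	Pacific Marten	63	n/a	n/a	n/a	n/a	n/a	n/a
Carnivora	Mustelidae	Martes pennanti	Fisher	3	0	0	n/a	n/a	n/a	n/a
Carnivora	Mustelidae	Mustela erminea	Ermine	1022	0	0	n/a	n/a	n/a	n/a
Carnivora	Mustelidae	Mustela nivalis	Least Weasel	187	128	2	100.0	99.5	36.9	1380156
Carnivora	Mustelidae	Mustela vison	American Mink	2096	0	0	n/a	n/a	n/a	n/a
Carnivora	Ursidae	Ursus americanus	American Black Bear	1376	45	7	97.3	88.7	68.7	885708
Carnivora	Ursidae	Ursus arctos	Brown Bear	2215	0	0	n/a	n/a	n/a	n/a
Chiroptera	Vespertilionidae	Lasionycteris noctivagans	Silver-haired Bat	7	4	3	85.7	33.3	50.0	28144
Chiroptera	Vespertilionidae	Lasiurus cinereus	Northern Hoary Bat	5	5	5	n/a	0.0	n/a	10164
Chiroptera	Vespertilionidae	Myotis californicus	California Myotis	48	35	35	100.0	4.2	50.0	20047
Chiroptera	Vespertilionidae	Myotis keenii	Keen's Myotis	49	16	16	73.5	0.0	75.0	27931
Chiroptera	Vespertilionidae	Myotis lucifugus	Little Brown Myotis	1001	78	38	100.0	81.0	42.1	482127
Chiroptera	Vespertilionidae	Myotis volans	Long-legged Myotis	11	6	6	81.8	18.2	66.7	21820
Chiroptera	Vespertilionidae	Myotis yumanensis	Yuma Myotis	15	15	15	n/a	0.0	n/a	96
Eulipotyphla	Soricidae	Sorex cinereus	Masked Shrew	14062	489	70	95.2	94.5	87.5	1360126
Eulipotyphla	Soricidae	Sorex hoyi	Eastern Pygmy Shrew	545	46	23	95.4	69.4	53.9	835981
Eulipotyphla	Soricidae	Sorex minutissimus	Eurasian Least Shrew	58	6	6	100.0	10.3	34.1	877425
Eulipotyphla	Soricidae	Sorex monticola	Southern Montane Shrew	6640	0	0	n/a	n/a	n/a	n/a
Eulipotyphla	Soricidae	Sorex navigator	Western Water Shrew	43	7	1	95.3	53.5	58.3	279397
Eulipotyphla	Soricidae	Sorex tundrensis	Tundra Shrew	962	98	15	100.0	99.5	66.1	1228386
Eulipotyphla	Soricidae	Sorex ugyunak	Barren Ground Shrew	296	31	26	100.0	66.2	69.4	392567
Lagomorpha	Leporidae	Lepus americanus	Snowshoe Hare	1153	53	22	99.5	94.8	57.5	1163852
Lagomorpha	Leporidae	Lepus othus	Alaskan Hare	263	35	19	96.9	90.5	58.8	235843
Lagomorpha	Ochotonidae	Ochotona collaris	Collared Pika	559	46	14	100.0	81.9	42.2	245866
Rodentia	Castoridae	Castor canadensis	North American Beaver	767	82	36	100.0	87.2	42.7	770478
Rodentia	Cricetidae	Clethrionomys gapperi	Southern Red-backed Vole	1438	0	0	n/a	n/a	n/a	n/a
Rodentia	Cricetidae	Clethrionomys rutilus	Northern Red-backed Vole	19645	98	4	99.6	99.6	91.3	1186737
Rodentia	Cricetidae	Dicrostonyx groenlandicus	Nearctic Collared Lemming	686	0	0	n/a	n/a	n/a	n/a
Rodentia	Cricetidae	Lemmus trimucronatus	Nearctic Brown Lemming	2025	0	0	n/a	n/a	n/a	n/a
Rodentia	Cricetidae	Microtus abbreviatus	Singing Vole	3330	161	34	98.6	97.3	40.2	833300
Rodentia	Cricetidae	Microtus longicaudus	Long-tailed Vole	1962	66	6	87.9	64.3	64.7	197887
Rodentia	Cricetidae	Microtus oeconomus	Root Vole	13513	0	0	n/a	n/a	n/a	n/a
Rodentia	Cricetidae	Microtus pennsylvanicus	Meadow Vole	3844	187	6	99.3	98.2	67.0	711267
Rodentia	Cricetidae	Microtus xanthognathus	Taiga Vole	2923	3	3	100.0	30.6	61.4	399796
Rodentia	Cricetidae	Mictomys borealis	Northern Bog Lemming	791	74	2	95.2	95.2	63.4	757297
Rodentia	Cricetidae	Neotoma cinerea	Bushy-tailed Woodrat	4	0	0	n/a	n/a	n/a	n/a
Rodentia	Cricetidae	Ondatra zibethicus	Common Muskrat	973	6	0	96.4	95.7	41.2	1186526
Rodentia	Cricetidae	Peromyscus keeni/maniculatus	Northwestern Deermouse	7924	4087	1047	94.4	94.4	100.0	65988
Rodentia	Cricetidae	Phenacomys intermedius	Western Heather Vole	3	0	0	n/a	n/a	n/a	n/a
Rodentia	Dipodidae	Zapus hudsonius	Meadow Jumping Mouse	451	142	13	96.0	77.4	62.0	843891
Rodentia	Dipodidae	Zapus saltator	Western Jumping Mouse	53	10	0	100.0	100.0	80.0	32563
Rodentia	Erithizontidae	Erethizon dorsatum	North American Porcupine	305	7	4	96.4	93.4	48.6	999216
Rodentia	Sciuridae	Glaucomys sabrinus	Northern Flying Squirrel	570	432	64	62.6	20.7	34.4	223535
Rodentia	Sciuridae	Marmota broweri	Alaska Marmot	85	11	1	100.0	52.9	33.3	283303
Rodentia	Sciuridae	Marmota caligata	Hoary Marmot	440	32	18	89.8	83.0	63.2	472592
Rodentia	Sciuridae	Marmota monax	Woodchuck	106	32	9	100.0	100.0	39.1	20223
Rodentia	Sciuridae	Tamiasciurus hudsonicus	North American Red Squirrel	2254	168	65	99.7	74.6	72.1	822276
Rodentia	Sciuridae	Urocitellus parryii	Arctic Ground Squirrel	2304	0	0	n/a	n/a	n/a	n/a
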