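site,month,depth_m,temp_c,salinity_ppt,silt_clay,median_grain,sorting,organic_pct,dd_km
1,Sep,2.62067760110324,16.2016276161184,16.5490543677208,0.353348189664162,61.6594282959897,1.43218913352155,2.14103212505895,0
2,Sep,4.56709174377592,16.7877360009772,19.8182896787742,0.494708527292496,195.765980642623,1.6660381153313,1.64207169875043,1.164
3,Sep,2.65086185205944,17.1969991499189,17.2881146312747,0.38666672722605,172.892744116859,2.11617653687407,0.428904777913589,1.298
4,Oct,4.67697524608206,11.3100371451724,18.8068510831384,0.399794077423367,112.372813706608,1.51294472193859,2.80094766841606,1.731
5,Oct,2.23498088560172,13.0620048472989,19.1025229753378,0.382319123890548,157.400867287569,1.29215248541221,1.58045143504032,2.179
6,Oct,3.8335123146838,12.2101392940646,18.4671892404187,0.407720942231239,81.4209474672312,1.27255387879623,2.01111610507111,1.686
7,Oct,2.82860113619601,10.8369727116145,19.1284346630301,0.395180628838075,207.644450156366,1.48903269624637,2.36608687241073,2.463
8,Oct,1.71882236338887,10.1683701556443,20.5350741382663,0.376760349517858,177.894998690949,1.47274488394634,1.23451349799068,2.97
9,Sep,2.2316255075689,14.8843425936273,19.9123256611813,0.382857568737924,134.441592454526,1.52918815622048,1.79353919276296,3.433
10,Sep,3.4253756001053,17.4429840627517,20.2363291762712,0.390850629703787,236.3771390505,1.54082587222273,1.47404764951755,3.79
11,Sep,2.12886365462245,18.6456686029108,19.5857967326176,0.259014483351061,116.406607186581,1.56097818980891,3.15696406105265,3.358
12,Sep,4.3077961495257,16.1737862693934,21.3601282213649,0.402949847173081,178.731583252307,1.46903080719321,4.21641932339537,3.88
13,Sep,3.80352380734823,16.136594022365,20.0772169700115,0.803442812593072,156.052865799585,1.25943644837194,2.21889630043344,4.119
14,Sep,3.43040703956092,15.6638347906754,20.119181271226,0.552817705009861,141.672913629195,1.4741509166104,3.65043508019736,3.642
15,Sep,4.30579606003115,19.0183790996008,20.8804802727385,0.286002236398857,136.935125780886,1.54570183774152,2.59264177988508,4.179
16,Sep,4.092921511147,13.7796326201038,21.5391745615192,0.343082963105038,208.016003378165,1.95639034329778,1.93155587613064,4.701
17,Sep,1.86699990327532,15.9455013071095,21.762714540352,0.375652242358125,108.212610873694,1.75847517401074,4.69174717441158,5.06
18,Sep,1.28250217348114,16.4267070194467,21.853642877378,0.343924933061363,231.77730367423,1.59330633201769,2.55959291049577,5.448
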