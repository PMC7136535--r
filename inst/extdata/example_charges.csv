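frame,atom_index,element,q_singlet,q_triplet,q_quintuplet
0,0,Fe,1.83234158706085,1.92781107843064,2.13104829667558
0,1,N,-0.647552083485221,-0.64258353073452,-0.631501999157071
0,2,N,-0.627961723485983,-0.632954584819659,-0.663267760292654
0,3,N,-0.197387835898341,-0.196621923035477,-0.191509558096412
0,4,N,-0.183071665729017,-0.194629981582692,-0.236838631317861
0,5,C,0.131294933823774,0.121675745001188,0.12160056733717
0,6,C,-0.134706547723412,-0.133177592157795,-0.131031201195246
0,7,C,0.128829383264085,0.109081168703835,0.113198218235178
0,8,C,0.617072006458649,0.6162097353693,0.612830947718176
0,9,C,-0.612402610541617,-0.624828391610938,-0.640863934875544
0,10,C,0.586696395941616,0.599477802024499,0.612152957657716
0,11,N,-0.125639834218364,-0.105744064314204,-0.17580667082891
0,12,O,-0.318872393030118,-0.398414911230196,-0.438648258163659
0,13,O,-0.448639612436897,-0.44530055004398,-0.481362973696463
1,0,Fe,2.01036863048678,2.10888816318319,2.29262288100749
1,1,N,-0.634271633715031,-0.624346599183307,-0.618374060069495
1,2,N,-0.607823484600576,-0.597007145477751,-0.639749231313126
1,3,N,-0.2279290195468,-0.206271736150119,-0.217933338630025
1,4,N,-0.172371878568393,-0.210517198202248,-0.213219258231578
1,5,C,0.126459030744379,0.112126297423835,0.107495128487988
1,6,C,-0.137479105540071,-0.120396085776744,-0.139962524608717
1,7,C,0.117971182901577,0.140383917872493,0.131888850862329
1,8,C,0.612933546193819,0.600122046967263,0.626188053659921
1,9,C,-0.60453381525809,-0.632720030206772,-0.657715045414114
1,10,C,0.590410077421587,0.585832449002067,0.612215034665276
1,11,N,-0.203486677615922,-0.212148129037056,-0.258722627957334
1,12,O,-0.487914472654587,-0.543841123697416,-0.592201575405312
1,13,O,-0.382332380248667,-0.400104826717438,-0.432532287053304
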