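position,assignment,component
1022,CH2OH group vibrations of glycogen,glycogen
1045,C-O stretching coupled with C-O bending of C-OH groups (glycogen),glycogen
1064,C-O and C-O-C stretching of carbohydrate moieties (collagen),collagen
1080,C-C stretch (glycogen),glycogen
1084,C-O and C-O-C stretching of carbohydrate moieties (collagen),collagen
1155,C-O stretching vibration (glycogen),glycogen
1164,C-O stretching (collagen),collagen
1174,C-O stretching (collagen),collagen
1202,amide III,collagen
1230,amide III,collagen
1244,amide III (downshifted),collagen
1250,amide III,collagen
1278,amide III,collagen
1304,amide III,collagen
1340,CH2 of collagen,collagen
1378,CH3 deformation (paraffin),paraffin
1404,CH3 of collagen,collagen
1462,CH2 deformation (paraffin),paraffin
1548,amide II,protein
1655,amide I,protein
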