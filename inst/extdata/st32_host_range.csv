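strain_id,species,pathogenic,d0,d2,d4,d6,score
HER1022,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1024,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1025,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1036,Escherichia coli,FALSE,TRUE,TRUE,TRUE,TRUE,++++
HER1037,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1040,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1077,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1128,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1129,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1139,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1144,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1155,Escherichia coli,FALSE,TRUE,TRUE,TRUE,TRUE,++++
HER1213,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1217,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1218,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1219,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1221,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1222,Escherichia coli,FALSE,TRUE,TRUE,TRUE,TRUE,++++
HER1240,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1252,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1253,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1271,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1275,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1290,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1299,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1315,Escherichia coli,FALSE,TRUE,TRUE,TRUE,TRUE,++++
HER1337,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1366,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1374,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1375,Escherichia coli,FALSE,TRUE,TRUE,TRUE,TRUE,++++
HER1382,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1383,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1392,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1393,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1445,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1446,Escherichia coli,FALSE,FALSE,FALSE,FALSE,FALSE,-
HER1462,Escherichia coli,FALSE,TRUE,FALSE,FALSE,FALSE,+
HER1536,Escherichia coli,FALSE,TRUE,TRUE,TRUE,TRUE,++++
HER1176,Escherichia coli,TRUE,TRUE,TRUE,TRUE,FALSE,+++
HER1255,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1256,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1257,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1258,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1259,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1260,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1261,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1262,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1263,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1264,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1265,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1266,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1267,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1268,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1269,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1270,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
ST130,Escherichia coli,TRUE,TRUE,TRUE,TRUE,TRUE,++++
ST120,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
ST110,Escherichia coli,TRUE,TRUE,TRUE,FALSE,FALSE,++
ST100,Escherichia coli,TRUE,TRUE,TRUE,FALSE,FALSE,++
BW,Escherichia coli,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1043,Shigella sonnei,TRUE,TRUE,FALSE,FALSE,FALSE,+
HER1031,Shigella dysenteriae,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1020,Shigella dysenteriae,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1045,Salmonella paratyphi,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1038,Salmonella typhi,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1518,Citrobacter freundii,TRUE,FALSE,FALSE,FALSE,FALSE,-
CF4,Citrobacter freundii,TRUE,FALSE,FALSE,FALSE,FALSE,-
HER1516,Citrobacter freundii,TRUE,FALSE,FALSE,FALSE,FALSE,-
CF7,Citrobacter freundii,TRUE,FALSE,FALSE,FALSE,FALSE,-
CF8,Citrobacter freundii,TRUE,FALSE,FALSE,FALSE,FALSE,-
Sa1,Citrobacter freundii,TRUE,FALSE,FALSE,FALSE,FALSE,-
Sa6,Citrobacter freundii,TRUE,FALSE,FALSE,FALSE,FALSE,-
Sa59,Citrobacter freundii,TRUE,FALSE,FALSE,FALSE,FALSE,-
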