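resname,name,area
ALA,CB,47.6761556124092
ARG,CB,15.4727365180114
ARG,CG,14.088995853799
ARG,CD,23.7751805032858
ARG,NE,16.7455724165674
ARG,CZ,10.9441307078617
ARG,NH1,48.5279853704607
ARG,NH2,56.2742365563558
ASN,CB,20.2529315398361
ASN,CG,5.15757883933714
ASN,OD1,31.808939776862
ASN,ND2,46.4775071153708
ASP,CB,18.8691908756237
ASP,CG,4.90598962766216
ASP,OD1,28.0141890666399
ASP,OD2,50.8943036429792
CYS,CB,21.259288386536
CYS,SG,64.339817545519
GLN,CB,13.9632012479615
GLN,CG,14.2147904596365
GLN,CD,7.170292532737
GLN,OE1,44.6441260026133
GLN,NE2,53.4263500909532
GLU,CB,11.6988983428867
GLU,CG,14.9695580946615
GLU,CD,9.68618464948683
GLU,OE1,43.0815815925219
GLU,OE2,51.5639655330184
GLY,CA,27.5490186784106
HIS,CB,20.7561099631861
HIS,CG,3.39645435761226
HIS,ND1,7.40450481004682
HIS,CD2,29.184348554298
HIS,CE1,44.0281120431219
HIS,NE2,27.6814564437135
ILE,CB,1.25794605837491
ILE,CG1,16.3532987588739
ILE,CG2,37.6125871454099
ILE,CD1,63.4004813420956
LEU,CB,14.843763488824
LEU,CG,7.29608713857449
LEU,CD1,61.0103838311833
LEU,CD2,35.851462663685
LYS,CB,15.5985311238489
LYS,CG,12.5794605837491
LYS,CD,28.177991707598
LYS,CE,36.7320249045475
LYS,NZ,58.5525457286779
MET,CB,14.592174277149
MET,CG,11.8246929487242
MET,SD,46.5123264339481
MET,CE,67.8032925464078
PHE,CB,20.0013423281611
PHE,CG,2.64168672258732
PHE,CD1,14.088995853799
PHE,CD2,12.0762821603992
PHE,CE1,34.7193112111476
PHE,CE2,33.4613651527727
PHE,CZ,34.4677219994726
PRO,CB,29.184348554298
PRO,CG,31.3228568535353
PRO,CD,16.3532987588739
SER,CB,29.5617323718105
SER,OG,34.9340285970449
THR,CB,10.4409522845118
THR,OG1,30.0231747367575
THR,CG2,50.192047729159
TRP,CB,19.8755477223236
TRP,CG,2.76748132842481
TRP,CD1,23.7751805032858
TRP,CD2,2.8932759342623
TRP,NE1,26.3144709403202
TRP,CE2,6.41552489771205
TRP,CE3,7.79926556192446
TRP,CZ2,33.5871597586102
TRP,CZ3,26.5426618317107
TRP,CH2,35.4740788461725
TYR,CB,20.1271369339986
TYR,CG,3.01907054009979
TYR,CD1,14.592174277149
TYR,CD2,11.8246929487242
TYR,CE1,32.2034190943978
TYR,CE2,29.6875269776479
TYR,CZ,7.170292532737
TYR,OH,52.1220171080511
VAL,CB,11.0699253136992
VAL,CG1,40.0026846563222
VAL,CG2,37.7383817512474
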