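c1ccc(-c2nc3ccccc3[nH]2)cc1	fix_01
Cc1ccc(-c2nc3ccccc3[nH]2)cc1	fix_02
Clc1ccc(-c2nc3ccccc3[nH]2)cc1	fix_03
Fc1ccc(-c2nc3ccccc3[nH]2)cc1	fix_04
COc1ccc(-c2nc3ccccc3[nH]2)cc1	fix_05
CCCc1nc2ccccc2[nH]1	fix_06
CC(C)c1nc2ccccc2[nH]1	fix_07
c1ccc2[nH]c(C3CCCCC3)nc2c1	fix_08
c1ccc2[nH]c(CCN3CCOCC3)nc2c1	fix_09
c1cncc(CCc2nc3ccccc3[nH]2)c1	fix_10
FC(F)(F)c1ccc(-c2nc3ccccc3[nH]2)cc1	fix_11
OCCc1nc2ccccc2[nH]1	fix_12
CC(=O)NCCc1nc2ccccc2[nH]1	fix_13
Cc1cccnc1-c1nc2ccccc2[nH]1	fix_14
CSCCc1nc2ccccc2[nH]1	fix_15
c1ccc2c(-c3nc4ccccc4[nH]3)cccc2c1	fix_16
O=C(Cc1nc2ccccc2[nH]1)N1CCCC1	fix_17
COCCCc1nc2ccccc2[nH]1	fix_18
Cc1ccc(-c2nc3ccccc3[nH]2)o1	fix_19
CN(C)CCc1nc2ccccc2[nH]1	fix_20
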