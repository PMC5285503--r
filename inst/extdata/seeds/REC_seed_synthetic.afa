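>REC_syn_01
LLIKAELAVS-PNNCKAGHIHAWQRLKVNGGWFVI-EELECPSLQSVIALILEVNSRPGA
SLVRFSQDMGPYFAVFFWQIDAVAESHLDTASVYPAKTLCDLIVQPEAKETS
>REC_syn_02
GLDDIELAVSHPNNRKLGRIQIWDRLKVNGGWFVIREELECPSFQSVQALILEVNSRPGA
SLVRFS-DMIRLFFVFFWQIDAVAESHKDTALIYTVKTISDLIVQKTAKLTS
>REC_syn_03
GGIDYELAVSHPNNCKSGHIQAWDRLKVG-GWFVIREE-ECPSFISVIALILEVNSRPGA
SLVRFSQDMLPYFAVFFWQIDAVAES-LDTASMYPAKTLCDLITEPTA-LKS
>REC_syn_04
GLIDANLFVSHPNNCKSGKIHAWDRLKV-GGWFVIHEELECPSFQSVIALQLEPNSRPGA
SLVRFSQSMLIYFAVFFFQIDEVAESH-DTAS-YIAKTLCDLIVQPTAWLTS
>REC_syn_05
-LIDA-TAVSHPNQCKSGHRQVWDRLKVNGGWFAIREELHVPYFQSAIALILEFNSRPGA
SLVNKSQDMLPQFAVFFWQIDA-AEIHLDTASIYPVKTLCDLIVQPK-KLTK
>REC_syn_06
GLIDAELAVSHPNNCNSGHIQA-DRLVVRGGWFVIREELECYSFQSVIALILEVNSRPGA
SLV-FSLDMLYKFAVFFWQIDAVATSHDDTASIYPAKTLCDLILQGTEKLTY
>REC_syn_07
-LIDAELAVSHF-NCKLGHIQAWDNGKVVGGWFVIREEQNCPSSQFVIAL-LEVNSRPGA
SLVRFSQDMLPYFAVFFWQIDAVAGSHLDLASIYPAKTLCDLIVQNTAKLTE
>REC_syn_08
GLIDAE-AVSHGNNCKSGHIQAWDRLWVN-LWFVIRKILECPSLQSVLALILEANSRPGA
-LVRFSQDMLPYFAVFFWVIDAVAESHLDTASIYPAKTGCDLYVGPTAKLQS
>REC_syn_09
ELLDAELAVSAPNNCVSLHIQAWQRLKVNGGWFVNPEELECVSFQSVIALKLEVSSRPGA
SLVRFSQDMLPYFAVFFWQIGAVAESHLDTASIC-AKRHCKLIVQPLAKLTS
>REC_syn_10
Q-IDAEGAVS-PNNCSSGPIQAWDRLKVNGGWFVIREELACPSFQ-VIALIEIVKDRPGA
SLVRFSQDMLPYFAVFFDQIDAVAESALDNASIYPAKTLLDLIVQT-AKLTS
>REC_syn_11
GLIDAELSTSHPNNCKSGHLQAWDSLKVNGGWLVIREELECPSFQSVIALILTAN-RPGG
LLVRFSQDMLSYFAGFFWCIDAAAESHLDTDSSPPALTLCDLIVFPTAKLT-
>REC_syn_12
GLIDAELAVTHPNNCKPGHIKAWDRLKANGGWQVIREELECPSFPSGIALILEHNSRPGI
SLVRASQNMLPYFAVFFWQIA-EAESALDGASIYP-KTLCDLI-QPTAKLTK
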