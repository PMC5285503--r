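>GAF_syn_01
LNKQIQCQVGYSYAL-AQQNVVATNRIYPVRGAWYTADTIAEIAVRRDDIPIFRLRGQSH
I-MPPADAPLSAFQTG-DNYNVDAE-L-SHLSNFEDVATFV-NDVEHTDPSKSIAKSQLA
KATGTSQILVFFCGEFGTIA
>GAF_syn_02
LNKQPQCQVGYLYALRESQN-VATNLMYPVRGLWYTADTIAEIAVRRFD-PLFYKRGQSH
IGMP-A-ATLNAF-TGWDNVNKDAAAL-AHASTFEDVATFVFRDVHHTDPSKSIAKSQLA
LATGTSQILVPFMGEFGTII
>GAF_syn_03
ANKQIQCQVGYPYALRARQNVVWTNLMYPNRGLWYTADTIAEIDVRRDGRPQF-EIGGIH
IGMPPADSPLNAFSTGWDNLNVDAAAGGSHYSAFIDSATFVFNDVEHTDPSKSIAKSQLA
LKTGTRQIAVFFCGEFKTIL
>GAF_syn_04
LNKQIQCQVG-SYALRGRQNVVATNLPYPVRG-WYT-DTIS-IAVRRDDQPQFRERGQSH
KGMPPANASGN-FATGW-NYNIDAAGRLSHTSLFEDV-TFV-NMVEHTDPSKSFAKSQLA
LATGTSTILVFFCGEFGTIA
>GAF_syn_05
LNKQIQIQV-ISYA-RARQNVVATILMYPVRGLWLTALTIAEIAVREDDIPQFRERGQSH
IGMPPADAP-NAESDLWDNYNVDAAAKGSHYSTFEDVA-LVFNDVEHTDPSKSILKSQLA
R-TGTSQILVFFCPMFGTIA
>GAF_syn_06
LNKQIRCQVPYSYALYAFQNVVATRLMYPVRGLWYTADTIAEISVRRDDIPLFREVGQPH
LGYPVADVPLNAISTGDVNYNVDAAALGSH-ITFEDVATFVFNDVEHTWPSKSIAK-QLA
LATGTSQILVFACGEFGTLA
>GAF_syn_07
LNKQIQCQSGYSYGLAARQPVVAVNLSYPVRGCWYTADTIAERAVRRDDTPQ-RERGQSH
IGIPAADAPLNAFSTGLQNYNVDAAALGSQYSTFIDVATFDFNDVEHTDPSGSIAKHQDA
LRTGTSQILVFFCGRFKTIA
>GAF_syn_08
LNKQIQCFVKYSYALRARQNVVATNLMYPVA-LW-NAQVFAEGAVARDDGP-FRERGQSL
IGMPPADAPLNAFSTGWDNYNVDAAALGYHYSTTEYVATFVFNDVEHTDPSKSKA-SQLA
DGTGTSQLLVFDGYEFGDIA
>GAF_syn_09
LNKQIQCQVGY-YALRGRQNVCATNLMYPVRGLWYTADTDAEIAVRRDDRPQFRERFQST
IGDPPADAPPNAISTGLDNYSVDAAALGSHYSTPEDVATFVFNDVEH-DPSKRIELPQLL
LATYTSQRLLFICGEFGTIA
>GAF_syn_10
LNKQIFCQ-GYSVALRARQNSVATNLMYT-RGLWYTADTQAEIAVRIDDIPQFDERGPSH
IGMPPAQAPLAAFSEGGTTYLFDLAALHSHYSTFKEAATKVFNDVEHTDPQKSQAKVQLA
LATGTSQILVFFCGEFGYIA
>GAF_syn_11
LNKQIQCQVGYSYALRAKQNVVATNGMYPVRHLWYTADT-REIELRRDDIPQFRELGQSH
IGMPIADAPLNAFSLGWDNYNVRAAALGSHYSDFNDN-QFVTNDVLHTDPSKSILKSPLA
LATSTSQILVFFCGEFGTVH
>GAF_syn_12
LNKQYQCQVGYS-ALRARSNVVTTNLMAPVTGLVYGADTIAEIAVRRDDIPQFRERGQ-H
IGMPPADAPLNAFSTGWDNTNVDAADLHSGYSKFEDTATFVFNDVERTDPSKSLAKSQLV
EATGTSQIFV-FCGEFGAIA
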