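>EBD_syn_01
IALLLLVFLIIILVIILIAIANQPPSSKPLSEEDNKTR-KDSARGRQVPQSLLIVLCVAV
HALVIVLIIIVIGLKDSDQECSDKGPADEASDPTPEEDKKKAIIVLVYIVLFILLVLLIF
LIL
>EBD_syn_02
IAL-LLVFLIILLVIILLLIANQPPSDKPVSEIDNK-RAKDEARGGQNMQSLAIVLCVAV
HAVI-VLILIVIGPESEDQE-SEKGYEDEASPPTPG-NSKSEILVVFYIILFILLVIIII
LIV
>EBD_syn_03
IALLLLVFLLILLVIILIAIANQPPNDKPSSFEDNSTRA-DEARGRQQPQSLLIVLCVAV
HALLIVIIIIVIGPEDSDQ-P-EKGPADELSDPTPGEDSKKAIVIVVYIVL-IALVLLII
-IL
>EBD_syn_04
IALLLVVFVIILLVIILIAIANQPPSDKPSSEEDNKTRAKKEERGRSQPQSLFIVLCVAV
HA-LIVLILIVLGPEDSTQEPSEKGPADEASKPTPKEDSKKAIIVAIYIVLFIALVLLII
LIL
>EBD_syn_05
LAILLLVFLIIL-VIILIAIANQGPSDKPSSEEDNKKRAKDEASGRQQTQSLLIVLCVAV
HALIIVLIIIVIGPEVSDQEPSFKGPADEASDPTVEEDSKKAIIVVVYIVLFIALVLLII
LIL
>EBD_syn_06
ILIFLLVFL-ILLVIILI-AVNMPRSDAP-IEEDNKTRAKDEARGRKQPSSLLIVLCLAV
HALLIVVILIVAGPEDSDQEPSEKGPADEASDKTPEELSKKAIIVVVYIAIFIALVLIII
IIV
>EBD_syn_07
IALIL-VFVIILILIIL-AIANQPPSDKPFSEE-NKTRAKDEARGRQQP-SL-IVLCVAV
HALLIVLILIVIGDEDGDEEPSEKEPADEASDPIPEEASKWAIIVVIYIVLFIALVLLLI
L-L
>EBD_syn_08
IALLLFVFLFILLVIVL-AIFNQPPSDKPSSENDTKTRAKVSARGRRQPQDILIVLCVIV
HVLLIVLIVIVIGPRDSAQPPSELGPADEASDPTPEVDSKKLIIVFVYIVLFIALILLIL
LIL
>EBD_syn_09
IALLLLVFV-ILLVILLIIILNQPNSSKPSSESDQAK-AKLEIQLRQQPQSVLIVLCVAV
HALLAFLILIIIGPEDSDFEPSEKGPADEASDPTPEEDSKKAIIVVVYIVLFIALVVLII
LIL
>EBD_syn_10
IALLLLVFLIIVLVIILIAIA-QPKSDKLSSEEDNKSSAKDEARFRQQPQSL-IVLCVAV
HALLIVLIAIVIGPEDADQEPGEKYPADEASDPTPEEDSVKAIIVVVYIVLFILLVVLII
LIL
>EBD_syn_11
IALLLLVFLIILLVIILIAIANQPPGDQPSSEIDNKTRAKDRAAQ-QQPQHLIIVLCLAV
HALLIVLILIVIGPEDSRKEPSKKGPADEASDPNPEEDSYKAIIVIVYIVIFIALVLLII
LLL
>EBD_syn_12
IALFALVFIIILLVIILFAIANQPISDAISSEEDNKHRARYTAEGRQQPQSLFIVLCVAV
HALLIVLILLVVGP-DSDQEPSEKGPADNYSDPTPEEDSKKAIFVVVYIVLFIALVLFII
LIL
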