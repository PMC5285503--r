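>HAMP_syn_01
RGQSVTFRVIKTLVLDKVNQSTANYTVRVGDRKVAFLMKVWNVNFVNVPT
>HAMP_syn_02
RRQAVTSRVVKTLVLDKMFQSTAQYYVRVGVRYSAVLMVVWNVNFVNVPT
>HAMP_syn_03
RGQ-VTFRVIKTLVLDK-NQSTAQETVRVGPRKVAFLMVVWNVNFVNVTT
>HAMP_syn_04
RGQAVTVRVIKTRVLDKKNQSTAQITVRVGDRKVAFLMVA--VNFVYVPT
>HAMP_syn_05
RGQAVTFRVITTL-GDGVNQSTAQYTVRVGDRKVAFLLVVNNVNMVNVFT
>HAMP_syn_06
RGQAATFRVIETLVLEKVNQSKAQYTVRV-KRKVAVLKAVWNVNFQNVPT
>HAMP_syn_07
GGQAVTFRVIAKLALDKVNQSTAQYTVRVGERKVAFLMVVWQVNFVNVPT
>HAMP_syn_08
RSQAVT-RVIKTLVLDKVNQSTAQYTVRVGDSKAAFLMVVWNV-FVNVPT
>HAMP_syn_09
AGQAVAFLVLKTLVLDKGNQSTAQYTVLVGDRKVALLMVVWNVRFVNSPT
>HAMP_syn_10
RGQAVTREVIKTLVLDKVNQSAAQYTVRVGLRKVAILMVVWNVNFVSVPT
>HAMP_syn_11
RGQAVVFEEIKTLVKDKVDQLTAQTQVRVGDRKVAFLMVVFNVNFVNVPT
>HAMP_syn_12
KGQATTFRVIKTLVLD-VNQSGAQYTVVVGDRKVATLMSVWNVNFVNVPT
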