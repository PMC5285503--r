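>HisKA_syn_01
IVTVLPNFSREAINIHAIIELNSYATSYTNVDKA-KLTHIISEIVFP-SQAADAGAVHYT
VIDPSE
>HisKA_syn_02
IVTVLPNEAREAINIHGIIELNETATSPENVDKAGKLTHAIVLIVEPPSQYAHTGAVHYR
VIDPSE
>HisKA_syn_03
I-LVLALISAEAINIHGIIYLNSYATSPEEVDPAGKLTHAIVE-MFPPDLYAPAGAVAYA
VIDKSE
>HisKA_syn_04
IVTVLPNEYREAINIHGIIELKSYATSP-NVDKAGKLTHIIVEIRFRPSQYAHAGAVHYA
VIDPDE
>HisKA_syn_05
IVEVLDNENREAINTHDITELNIYA-SPENV-KADKCTHAIVLIVFPPEAYAKAGAVHYA
KIFPVV
>HisKA_syn_06
IVTVLPNESREATN-HGIIELSSYATSPENVDTAGKLTHAIVEIVFTPSQYACAGAKHAA
VIDGSS
>HisKA_syn_07
IVTVLPNESREAINIYGIIELNSYATSKENVDKAGKETHADKEIVGPPSQPAHAAAVHYA
VIDPSE
>HisKA_syn_08
IVDILPNESREAIDTHEIIELNSYATSPENVDKAGKLTHAIVEIVFEPSQYALVAAVHYA
VRDPIE
>HisKA_syn_09
IVTVLPNESREAINIHGEKELNSYATSPENQDKAGKLTHAHVGIVF-PSQYNHAGEVHIS
VIAPSG
>HisKA_syn_10
HVTVLCNDNREAI-IHGIIELNSYATSPENVDGAGKLTRAIVEIVFPPSTYAVAAAHHYA
VIDPSE
>HisKA_syn_11
IVTVLPNESREVIG-HGIIELNSDATSPENNGKAGKLTHAIVEIVFYPVQYAVAGAVHNA
V--VSE
>HisKA_syn_12
IETVLPNESRKALNIHGIIELNSYATMPWNVDKAGILIHAIVEIVFPPSRY-AAGA-FYA
IIDPSA
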