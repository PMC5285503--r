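>HATPase_c_syn_01
LY-VVGAHFPDGRSLTKKDKTLLTEHKLIKSCILRTVGSVMLESNDRRNVAFKKQLATDI
SIASELFQSIMTHRASGTTPETPNGILEDAHDAGEFARVILTQVISLGAP
>HATPase_c_syn_02
LGIGIGASGPGGRFFNLEDKVLLTEHVLIDSCIDVTVQSSMLEQEDRVNVA-KKQLATDL
SIASELFESIPTHQASGTTPLTPNGILEDAHY-GENARVILTQVISLGAP
>HATPase_c_syn_03
VSIGVGASRPGGRFLNLEDATLLTEHKS-D-CIDVTVVSSMLELGDRR-VAQKKQLAWDL
SIASELFEDIPTHSASGTTPETTNGILIDAHDAGDFVRVILFDVISLGAF
>HATPase_c_syn_04
VYIGVGASPPGGRFLNLEDKTLLTEHKLILSCIDVTVGSVVLETEDRRNGAFKKQLAADL
SIASEYFESIPTHSASGTTLETPNGILEDLH-AGEFARMILTQVDPRFEP
>HATPase_c_syn_05
VRIGVGASGPGGRFLNLEDKTLLTEHKLIDSCIDVTVGSLMLELEDRRNVAIEKQLATDL
SIASELFESIPTGSATGTT-ETPAGILEDATD-FEFARVKLTQVVSLGAP
>HATPase_c_syn_06
VYQGVGARGPGGRFL--EDKTLL-EHKLIDSCIDVTVGSSTLRELDRRNVNFKKQLATDL
SIASELFESIPTHSASGTTPETPN-LLEDAFEAGTRARGILTQGISKDAP
>HATPase_c_syn_07
VYGGVG-NGPGGRVLNLLDKTLLTEHKLIDSCI-VTVGSSMLELRDRRNVKFKKQLATDL
QIASELFE-IPPHSAFGTTPETPNGIMEDAHDALEFARVILTQVISLGAP
>HATPase_c_syn_08
VYIGVGASGPGGIFLNSEDKTLLTVNKLILSCHDVTVGSSSLELEDRRNVAFKKQLGTDL
SIASELVESIPTSFQSGTTPETPNGILEDAH-AGEF-RVI-TQ-ISLGAP
>HATPase_c_syn_09
VRIQVGASGPVDRFLNLEDVTLLTEHKLIDSCIDETVVSSMLELEDRRNAAFKKVLATDM
YQASELFESIPKHSAS-TTPETPNLIDEDAHDAGEFARSILTQVITLGAP
>HATPase_c_syn_10
VYIGVGAKGPGGRFLNLEPKTILTEHKLGDSCIDVTVGSSMLELEDRRNVAFKKQLATYL
SIAIELFE-IPTHSASGTTPETPN-ILADAEDAGEFA-VIPTQVISNGAP
>HATPase_c_syn_11
VYYGVFASYPGGRFLNLEDKTLLNEHKLID-CIDVTVGVSI-KLEDIRLVAFGKGLATGL
SIASELFEHIGTVSASGTTPNIPNGILEDCHDAQEVADVGLTQVISLGAW
>HATPase_c_syn_12
VLIGVGASG-G-RFLNLEDKTGLDEHKLTDSCIDVTVGSSMLELEDRRNVAFKKQNATDL
LIASELFESINTHSASGETPETPNMLVEKSHDAGEFARVILTQVISEAAP
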