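>CHASE_syn_01
LGTIVKSALEQEAEIEDVEDLKPGRGDFNFRLALPMRSNKQPPV-IGQ-MGLVAIIQGSA
MYD-VAGMKAGERQLHFYDDAVLCILDFVKSDTSAVAVVKDIPQRYAALGFERDYRSRDR
TWRIIYIRVLMDEELDTKVKEPTMERIRYLPPAYADT-APTNARRGLFRAE-ESDTPNKI
NLCIWATRFR
>CHASE_syn_02
LGKDNKLFLEQEAEIEDVEDLEDARAHFNFREALPMRSNKQMPVSILQSMGTVANLLGYA
VYDQVKGMKA-ERYKHFHDDAVLCILIFVKMDVSAVAVWKNIPQAYAALGFERDCRSRGR
-W-ITYVRVLMEEELDTKFAEPTPERQPSVPPEGADK-VTTLAKRGLFRAEPESDTPNKI
NLKGWATRGR
>CHASE_syn_03
LSKIVKNFLEQEAEIEDVVDL-DAR-DFNFRNALPSRDNKQMPVCKGQSMGLVSIIQGKA
RYDQVKGMDAGERQLHKHDDAVLCILIEVQMDTSAVAVVKVIPQRYAALGFER-CRSRGR
TDRIVYIR-SMKEELDTKFKESTPERIRHDPPEGADKVVTTNAKRGL-RDEPEVDTPNKI
NLKIWATRGR
>CHASE_syn_04
LRKIVKNNLEWEAEIEDVEDLKDARVDF-FGLALPMRSNKQMPVADGQSMGLVAIIQGYA
RYDQV-GMKGTELQLLFHHDAVLCILIFVKMDTSAVAVVKNILQRYAALGFE-DCRIRTR
KWRIVYIRANMDEILDTYFKVPTPEGIRHLPPEGADKDVTTKAKRGLFRAEPESDTPNKI
SGKEWATRGR
>CHASE_syn_05
LGKIVKNFLEQEAEIEDVESLKDLRGDFNFRLDLPEAANKQMPVGIAQSMGLV-DIQGLA
RYDQVKGMRAGERQDHFHDDAVLCIL-FVKMDTSAVTVVKVIPQRYAALGFERDCRSRGR
TWRIVYIRKLMDEELDRKFKGPTAGRIRHLPPEGADKDVTTNAIRGLFLAEPLSDTPEKI
NLKIWATLGR
>CHASE_syn_06
LGKIEKNFLEQEAEIEDVEDLKDAGEDFNFRLALPMRSEKNMPVAHGQSEGLVLIIQGYA
RYDQVKGMKAGERSPLFHDDAVICILIFVKMDTSAVAVVVNIPQRYAALGFDRDCYSRGR
TWNVVYIRGLMYEELDTKFKTPTPEEIRHLPPEGAAKDVTTNAKRGLFRAEPESDTPNKI
NLPIWATRGA
>CHASE_syn_07
RGGIVKNFLRQEAEIEDLEDLIDARGDFNFRLALPMRSNK-VPVAIGQSSGLVAIIQGYE
QYDQVTGMKAGERQLAFHDDAVLLILIFVKMDTTAVAVVKNIPQRPAALGFERDCSSR-R
TWRIFYKRVLMDEELDTLFKEPTPERIRHLPPEGFDKFVTTNAKRGLFTAMPESDTPNKI
NLKIWAARGR
>CHASE_syn_08
LGKIVKNFLEQEAFIVD-EDLKDARGDF-FRLALPMRSNKQMPVAIG-SMGE-AIMQGYA
RYDQVKGMKAWERQLHFHDDRKLCILIFVKPDTSCVAVVKLIRQTYAALGNERDCRSRGR
TW-IQYIRVLMDEELTKKFKEPTPERLRHLPPEGADKDVT-SEKRGMFRAEPWSDTKNFI
NLKEWATRGR
>CHASE_syn_09
LAK-VKNFLEQEAEIEDVEDLKDAIGDFNFTLALPMRSNKQM-PVEGQSMGLVAILQGYA
RYDVVEGMKAGERQLGFNDGAVLCLLIFVK-DTSAV-VVKNIPSRYAALT-ARDCRSRGR
TNRIVYYRYLMDEKLDTKAKEPTPERIRHLPPEGADKGVTTRA-QGLFRAEPESITPNKK
KSKIWATYGR
>CHASE_syn_10
LDLIVANFLQQEAEIEDVEDLKDA-GDFNFALALA-RSNMQMPEAIGQSMGIVAIIQGYA
RYDQVKQMKAGERQLHFADDAVLCILE-VKGDTSAVAVVK-IPQRYK-LGFERDCRSRGR
-WRIVYIRVLMSEELPTKFKEPTPERIRGVPPEGADDSVTTNAKRGLFRAEFESDTPNKI
NLKIWVTRGR
>CHASE_syn_11
DGVIVKNELEQEAEIILVEDLKDARGDFPFGGALPERVNNQMPVAIGQ-MFLVACIQGYA
RYDQVKGMKAAGRQLKFCADAVLDILINVKMDTSAVGVVGNIPQRYAALGFETDCRSRGR
TWRIVYIRVLMDEENDTKFKEPTPERSRHLPTEGADKDATTLAKRGLFDAEPISDTPNKI
NLKIWATRGR
>CHASE_syn_12
LLKIVKNKVEQE-EIEDVEDLKDTRGIFAFRLNLPMRSNQQMPVAILQSM-LVAIIQGYA
RYSQVAGMKAGERQLHFADDAVACI-IFVKMDTSAVAVVKNIPQRWAALGFELDCRSRGR
TWRIVYKRLQMDEELDTKFKKPTPERIRHLPDNGADTDVTTNAKRGLFIAEPES-TINAI
NTKIWTTRGR
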