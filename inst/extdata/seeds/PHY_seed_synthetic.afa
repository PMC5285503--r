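>PHY_syn_01
DFKDDVTRAPFMVLDSVILQMDIEHAQTIGEWFHTSPYKSEFLEGNMMNDTQVGILGPFS
LIL-QMMVCVEGSIKAAWDVDVGSTKIREGGDVYL-LLCS
>PHY_syn_02
DMKDDVTVAPSMATDREILDMDIEHARSGGEWFFSSPYKSEELEGNMMCREQVAILGPDS
LILVQMMSCVEG-IEAAWPVDGG-T-IRETTDVYLTLLCS
>PHY_syn_03
DMKDDVIVGPFRATDYLILQMDSLHARTGREWFHSSPYKSEELE-N--FQTQVLILGPIS
LILRQ-MACVEGSIEGAWQVDGGSTKIRLTTPVYLILLDS
>PHY_syn_04
DLKLKWTVAGFMATDSLILQMDVEHARTVEEWFHSSPLKSEELEGNMMFDTQVAKLGTES
FSLRQMMSCNEGSKEAAWDVDGGSTKIRETTDVYLTLLCS
>PHY_syn_05
WMKADVTVAPFMATDSLILQMDIEMARTGG-WFHSSPYPKKELYGNMMLDLQVAILGPES
LILRQMMVCSEGSIEAAWDVKGGSLKIRETTDVPLTELCS
>PHY_syn_06
DMKDGVTVAEFMATDSAILQM-IEHAREGGESFHSSPYKSEELEGAMMIDTLVSFRGYES
L-LDQRMSCVEGSSEVAWDVDGKSTKIIETTDVYITLLCS
>PHY_syn_07
-MKDAVTVAPFMATDSLILQMDIEHARTWGEWFVSS-YKSEELE-NMMFDTQVAISGPES
LILRQMMSCVEGSIPAAWQVDGGSTIIRETTDVYLTLLCS
>PHY_syn_08
EMKDDVTQAPFMALMSLILQMDIEHART-MEWFGASPYKSEELEGQM-FDTQVAILGPES
KILRQMMSLVEGEIEAASDV-GGSTKIRETTDVYLTLLCS
>PHY_syn_09
DVKADETVAP-AATDSRILQFDIEHARTGGEWFHSSPYKSEELERLMMIDWQVAILGGES
LILRDMKSCVEGSYRPAWDVDGGSTK-RETTGVYLTLLCS
>PHY_syn_10
D-KDDVTVAPFMAKDSLRLQMDIEHAGTGGEQFHSSPYKSEELEGNGMFDTQVAILGPEV
LILRSEMSCVEGSIEAAMDVDGRSTKIRETTDVYLTLYCS
>PHY_syn_11
DMKDDVGVAPFMATRSLILQM-IEHARTGGEWFPS-PYISEELEPNMMFDTQVEIVGPES
IILR-MMSCVPGSVEVEAYLDGGSTKIRETADVYLTLQCS
>PHY_syn_12
DMKGDVTVNPFMATDELILLSDGEHAGTGGEWDHVSPYESEEEEGNMMFDTQVAILGLES
LILRQMMSCVEGSIEAQSDVDGGSTKIRTTTDVYLTSGCL
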