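>PAS_syn_01
HGLIV-GEGLRFAARKMSR-KATVPSIQPLWVAGPQLELAGTIVSSFPQNFRAWVGEKIE
HPEVMSSTWD
>PAS_syn_02
VKLIVARETLRFASDKMSRIKATVAKIQPLTVAGPQLELAGTSVSSFPQTFRYWANENDE
HPAIAYLA-D
>PAS_syn_03
HKLIVARETLRFASDKMSRSKANVASIKPLWVAGPNLELAGGSVSSFPPTIREWPNENDE
HPELMRITWD
>PAS_syn_04
G-LIVARETLRFALDKMSRSKAILASIQPLWVAGPQLELAGTSPSSFYQTKRYWPNENDE
HFELMVSTWD
>PAS_syn_05
HKLIVARETLRFASDKMER-KATVASILPLWVAGPQLELAGTSVESFPQTFRLWPNENDE
HPSGMSSTWD
>PAS_syn_06
HKLIVARETLRFASDKRSRGCATVASIQQLWVAGPQLELAGTSVSSFPQTFILKPNFEDE
EPELMSSTWD
>PAS_syn_07
HKLIVAYETLRRASDKMSSSKATVASIQPLWVTESQVELAGTSVSSFPQTFCYWPDENSE
HPKLMSTTWD
>PAS_syn_08
HKLI-ARE---FAGDKMSRSKATVASIQPLWRAGPQRELAKTSVSSLPETFRYSPNENDE
HPELLSSTWD
>PAS_syn_09
HKLIVARETLRFASDKESFSKALVANIYPLWVAMPNLELAGPSVGSFPQTFRYWPNANDE
HRGFMSSTWD
>PAS_syn_10
HKLI-LRETLRFASDKMS-SKADVASIQALWVAGPQLELAGFIVRSFPQTF-YWPNLQDE
HPEL-S-KKD
>PAS_syn_11
HKLIVAGETLRFASDKMSRSKATVASDQPLWVAGPPWEFAGMSVSSFVQTFRYWPNENDE
HPELMSSVSD
>PAS_syn_12
HKLIVAEEVLVFASD-MSRSKATVASIQPLWVAGPPLELAGRSVYSFPQTFRYWPNENDE
HPELMSSTWD
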