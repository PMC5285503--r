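>AtETR1_synthetic synthetic ethylene-receptor reference (EBD+GAF+hybrid core)
KASKDSTREEIALLLLVFLIILLVIILIAIANQPPSDKPSSEEDNKTRAKDEARGRQQPQ
SLLIVLCVAVHALLIVLILIVIGPEDSDQEPSEKGPADEASDPTPEEDSKKAIIVVVYIV
LFIALVLLIILILQEGDQQNEGDPKAGGEEEGESQGGGGSSDELNKQIQCQVGYSYALRA
RQNVVWTNLMYPVRGCWYTADTIAEIAVRRDDIPQFRERGQSHIGMPPADAPLNAFSTGW
DNYNVDAAALHSHYSTFEDVATFVFNDVEHTDPSKSIAKSQLALATGTSQILVFFCGEFG
TIAKNRDKTDEPPNSQGEGGGSAQSNNSTGDTGIVTVLPNESREAINIHGIIELNSYATS
PENVDKAGKCTHAIVEIVFPPSQYAHAGAVHYAVIDPSEAPGGSSKEQNGEAESEKAPRE
KPDAGNQARVYIGVGASGPGGRFLNLEDKTLLTEHKLIDSCIDVTVGSSMLELEDRRNVA
FKKQLATDLSIASELFESIPTHSASGTTPETPNGILEDAHDAGEFARVILTQVISLGAPP
TQGDPSSNGGNKDGNQKANPKGKRPEEGRGLIDAELAVSHPNNCKSGHIQAWDRLKVNGG
WFVIREELECPSFQSVIALILEVNSRPGASLVRFSQDMLPYFAVFFWQIDAVAESHLDTA
SIYPAKTLCDLIVQPTAKLTSETQSDQGPTA
>AtAHK4_synthetic synthetic cytokinin-receptor reference (TM-CHASE-TM+hybrid core)
APTATSSAEGRKDGDKQGADSPETDEDSDKSGSKKQKEPQTEKKSDETANSQGNPGQRGT
KPKKNPDDNSNKNGGGGKRAPASGDDPKEAPNPSALLLVIILVVVLLAIVIIIAIFPEEG
KGAEKLGKIVKNFLEQEAEIEDVEDLKDARGDFNFRLALPMRSNKQMPVCIGQSMGLVAI
IQGYARYDQVKGMKAWERQLHFHDDAVLCILIFVKMDTSAVAVVKNIPQRYAALGFERDC
RSRGRTWRIVYIRVLMDEELDTKFKEPTPERIRHLPPEGADKDVTTNAKRGLFRAEPESD
TPNKINLKIWATRGRKAEDKASPGKIIIIFVLAIALLLLVAFLLLLKQGEQEGDNEERST
KQGEAGSKPKKEGTRPIVTVLPNESREAINIHGIIELNSYATSPENVDKAGKCTHAIVEI
VFPPSQYAHAGAVHYAVIDPSEDRKESDGRSNKPQKDDSKQQAGGPADDASQVYIGVGAS
GPGGRFLNLEDKTLLTEHKLIDSCIDVTVGSSMLELEDRRNVAFKKQLATDLSIASELFE
SIPTHSASGTTPETPNGILEDAHDAGEFARVILTQVISLGAPDDEPEDTPGTKSKKEQRK
EQSEKKQNQQANGLIDAELAVSHPNNCKSGHIQAWDRLKVNGGWFVIREELECPSFQSVI
ALILEVNSRPGASLVRFSQDMLPYFAVFFWQIDAVAESHLDTASIYPAKTLCDLIVQPTA
KLTSKGKEKQDGGS
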