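>PRRC2B_L_synthetic synthetic stand-in (2229 aa, 164 R, 200 G, 15 RG: 11 in aa 775-1468, 7 in aa 1061-1124)
YCGKRDSLEARRKAYPRNNQRWERPYYVIQMNRGLVNSLAGRSAANQSFPHKYIAVCKCY
MGNKHEQAGFLGWQTPMKGHWHSRLQIWGRNAFCQCPKYGGVAGTVVEMTEYHDGYPFLM
GHREGQEFWFGMVGRHNLEKANCPGRPFDSCVWNNDDHKIKNFQTTCCHDCWENMNHLFY
EEMMEKFRRCFKLFVKGKDLGVEVYKTHMMYWNKYRPLLGQAYHMFNFMKSPYHNRHPET
AMRSLDHIVGLRHATRFLWGSGYLKHEWKNWDHADKTYQVQQGYARDSFYHDNAMKRALL
ACFSPAWDEFQQWVHREFWPRPDIWGVKLTEDGQSFCDGRRAARDRMQESHDHSGTIYDC
SKVRFKPLPMPQPRSDQMLANGRVWMEGPWKRWSMYRKGQDIITANCPLGWWPARVFQWG
FGLNSHVDHTIGIKCVYGWTGCEIFGRGYGFEMGNDMAGGVPLGDNPHCMGPIDCRNKSP
LSQNQRHHEVDQFDFSDSYQQHPYWQCDKSWVTTVVRWWRPAGWRMCGHTHREGSYIGTK
WPSEPDAIRIAYADFKEGCILCRWSRWECTHKGNPFSMWHGETGWCSGYRGHPFIAKEQT
KAGLTFHLPPSGYQSDTGGDRRVRDGEGNKAEGVHWMPTRQNEKRCRCYVFAKGHTNHTG
HLNRTDIRQYINNIWNKEGGIINCGIEGNKDFGPMPHRLAYVQYQNKHRGCFEEYAYKLV
NIFHGMVWGCRRRKHECIGNQGEAPMANCRRWYKKWNWMAHCDIMAWGTEVMYQNFEAMV
YQALIRDPIKFNMKCFYLQAIEDPINQPDVMQPPGPNRYGAMLRCGAPAYKPDDREDTGC
SQGGKNNPDKSKWLLQRAIPFQHSYADVHKALGANFMPITAHIKAPVFIANGAHMRFKED
RCGQEFIGMRVGPANQIFFCSKIDGKLKFPAHDKNPTARMIGRYAKHPRLIRGQGYFVGR
PVICGHRDAWAGILHGNYFEVRDMTYGRTVEKILYAEGYLAGDEGGHADQYYYHIQPCDC
GQDCGNFYWYDKDCFGCEQYCDRDYRVLTSNSYKGPSGVGIPCNRGYGRWVRGNDKERGP
GMNRGMPIWLVRGHFVARGHWTAYKVVIFGREPLITQDEVQRGKWPKCFGNDPYYSCLQE
RLKHRDGRPCRPAKIYAELWMWRPERGGCMIIWYIPSVEVYENESIIRGCNYHGWALKKA
KGNKPMMRCINQWTVHHQAPMFLEYHQASLRRGHCGDKSGDQDDRPWLDQYYMSRNGTGV
ETILAEHVCAMGICREYRHWSTTRWRPERAINKHYFDRTVNMTLHNRYAWDQVNVMVFDK
VGSVVQKLGEIEKCWLMCDLHSRYNPAGVHPVMLENGAEEFTKWYSCHEFAIRWPTSHSL
QNVHKAQGISQRRIIYIPRVLFVDKIACEPKRTAILEKGMAYHWRVKCMWHMSNGTQGHL
IYHGSWGFSKRNVMRYKCYQYVPELPVYIAMANTEETMLNNTDDKRCHGGPQHDGFRLEK
GQHPCFELPHLCRLEMEGYNQLQKWYNANGYQHHRFRTGDEALQDEFNSHRRVRQPGWHH
GIKFQCGYHYWHDKPMHPYQVRNKHAIGRKVKLELTIVKVNPSPQFVAGEGFLMCYCPTT
PYAWHHMERKCRPYVIGFMRVIIDMFAIALLTNVVQYRDPRRMPRQLKIKRMDCWPKVAQ
MIHAGRDGVGVRCITIMHDYLAQYYTRDSYTYKGVYHNRLPYHATRLKRVTRWCWESSMD
IAEERAASDGGPKRSQMPIRDPWKPMEGLRLHFMWTHGPCMHNVIEIFYTCVGCWPINFA
HMPYHIIWCYEPCKHIPCNGTIEEDCAADQGDHWFYGEFGDFTGQGFLPGTKGHWPGCGA
CTHSVVSHVGCFIEVITSMNGWASKQWIFAKYWGFIKFNQVRKGMFAQANRQFRFKHVFM
QQDIGFPGEDMHLNLNLWHAEFIQSFCASHFWIVYLAEGLYEDSYIFFNIHFRAGAPSSQ
RAGCCMGDSSSCFAYWHIDGCTCKDEGFFNWGGAPFFVGPVFMPKNHAIHYDWSCTHMDR
SEGCHYLLCFYGARFFKDIEPYYVYCIFAMIITMGKGVNAVKWPGEIEGMTKKRVRYYCA
IIYKTYSGRRPMEYYGDGCPHVQQMVPCEAIKGKIRRHWTVGRNSSSSHIMALICDRATG
HMWPESWRHNRKIQIDNIITMMTQHTTWQHYQIGDLGKQSNYQASHYTCETHNFEPHKWY
AEARRHRCE
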