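>AtACS7_like_synthetic_reference
HGLPWSIEHSTMMALDSGPDWCQMFFAFWYSPRCPATSQWAFSPKTVSRVMPYSTVSWQMTRDRSNPYHAYADKGWCASW
YGFPNDWIALSGDEMEMQYSNACSVGEVTVSHEHNQTQRPGYECDEHIESRFFSDYIYNEGESVINADFHCIWQDCFCKN
CRVVRCKNQVNWCQMCVDLHCKWYRILIHFKHGFELCWKRCICYANHGLINFDTYGNDIPGCPTGDEDYEMHTKRWNWGI
EASRGLWRSFICVVPENLHKFGEWFCEDPHPQMHYACMFLPELPTDRGSCFKEVTVEMMRVCCTLNWNMNIKYAIGCEHE
LRVMMWIHQITWCYTKPRNCPRAIGAPKVIPHLDQACDETMAHAHYYSLEMIDYNPQTVQPRSSRMGVMCLPWLAEVFLS
CPYNEYLSQ
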