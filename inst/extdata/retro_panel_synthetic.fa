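>gag_like_1 synthetic retroviral-like toy protein
MYAARDQISYKIPSCFSKKPRDTCGFCNMNGCYGSVAFRMCEWNKIAQTYACHRIFEPYW
GPVWEEFLANEIWLGLIWHNFRSGNDFWKKPGYLDSNSQHMWMDVQNILFPLERAKDNVM
AADKVIICVSAVETHCALKFPNYPSNLGACIQNTATMRFFWALVHWDPMDYASQSELPRD
>gag_like_2 synthetic retroviral-like toy protein
MAGRPAANLEFILGITATTHRKPDWGWMPVCLAVRKQWAPQTKHNICKDMDVVILWTRCN
QDEDYIWGDKPATMFREQWCFGCIAINFGPVRARWKQCKTDRDPTLQINQWEAPSKQLWI
CRPVDDLIRQCGGLQFGDQYDVWCRHAAFKRKRTAWPYKHQIDEAHRHDQNYIWLGWWSA
IEVTVGNKTGFGPFWPCTPLHNVFWNFMSH
>pol_like_1 synthetic retroviral-like toy protein
MWNYRGFPMITSSNLNQGRSLSQCIWANRSQTHHVYGKYWDTHYPQRHQVHDPNDYFQSP
IASYNGCFLNFKGFPDHGDPWMSITAKACESPLSHHKYRRLISGDHHAHAGVSIGNPIYY
EEKGTCLLTTIVQIQMFAHEQGQDETKARQAAWSATHAEKRMHQNVFEKIMVIECMCIWF
WFTPCNCLPMHWFIECSCRLYRAYVPQSPQHWFSHTHGMVIKPPNEPKEDHWAHFVHYME
>pol_like_2 synthetic retroviral-like toy protein
MGYYPLCTNSEIWWMHVRDRRKGPIFGCQEMDISTGACYQDRWPALEWYRRHIFNFQNCL
FRAIGFRPCGPICMAGWYWQWFSFVGFQLSFCMNTLNQRPDAEMYGPMHPCWCHMVLCLR
RETRTCDQPQKSKYCIVTYVFKRNAMNYYHNEEMSFQFTYFQPNEDCNASHHPDWYLFKM
YSTELPHKEGITENARSWLG
>env_like_1 synthetic retroviral-like toy protein
MNWYYRSGQGLHWISVYANWPKVSYLIQGDGMQKLPLQKHFLQVTRYHICFLMYASERYH
STSFHRNAKIIKQWFDYECMKIGICESEPWDHCANTRGSDCTLFYSQCEWEHCLCDTKQH
WFRWERKEMWEKLMEGENFVGPVIQLYGVPTGKSIYSPNF
>pro_like_1 synthetic retroviral-like toy protein
MDTLDLMNTWKYSCMQCRKIMTFTYNMKQNDKEDWREIWDEPGKIIKNDTGLAIWCLYNT
CQNDIWNVFQEQYRVKYRDKFPHRPRLDHRRIASEHFLQGMTKHPTWVGWYMYGLPWMGD
TIFTAWFCFNFRRLCAWVWQKIVTALLNSC
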