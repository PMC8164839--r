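>synthetic_VCL_surrogate synthetic surrogate; three tankyrase-binding motifs at 339/449/520
GMCCPKDPQIVYKTGIYFKCFCWIPWKSFQPFLSVSWTAKGCGLGYCAAHHADRDARWTI
YSQWFDVMVGIEAPHYATGTIDMHVHVLFYMAGDSIDIEFAGISFAFISCSLCELWKMRI
DCQVWLMQENKACLKQANFGMKWCVAVEHLEPENIPPYWTIGTLVHVDITVGAWLKELCK
HNCQNMRERKPFRKYPNADQMTKWFVSNGGWEYKICPRDIFKFQHISIMQDWCWEKSFMC
SDQANGKAMQMWYEWPVYDVNNVHGKGCHHDCNFVHMMFWLFFPNHVTVLSVAYIAEFSE
PEFNYFHGWIRRVINVRQIHMAWTCHVIWWTSCEEPMDRARGQGNNEAKRQSFHRATRAI
SEFANDPDPYEVDNGHERMAQWSTVYASLVDPSHLYTWMHKNLQEFLCMSCCHMDKSSSC
TANYCMQMWFFNEFHHHELKMGYYPGAMRRQGKGYKKKYQPTCNFEDLAMGFVVQIETVM
WKTGAPNWCCHVKHLEEYHMMVEHDDPFMWAYDLGTYKKRGLVAEGTAQCEDRAHCRART
HMPMDVAWSDRCVCNAQRRDNESHRGGFWSFYDKHIWMQPRDSCPQVIMRNKMINHYYRQ
VKDNKPAFESDYNVNKMCDNTLDAIHPYTMPGIQAIYCQVWFSVIRTIYMPWLEDNKEPV
VRFRCVHFNPYICCTGKWHVGDPKIGGRHTWTAGPCHWLFNLPDMENEFLFPIGIVNWYY
KRSPDSEVMIKPKMYHYTVKPDICLVYCRKLERYDEKHIAGTYILPFEFSSNMSLNIQQN
YLADTHSVQEWCYGFHDMQKCVTCWAYQTDSDMWVVMDQEYYSWEDHQIGPVCFCINFYF
DVYSNDCQGDTDERCQCQPCVYNTRDNEFERRQYNNLVTSPYYHAMYQQNCVKTTAGFPN
CVWFNGLKMGQYMCMNICPWTAMQMNFMDSTMFQHGRPKEILSLKGGPWTYHMTCQNLVE
QKPLMDPAWHLPWEIFAHGSPQHGIGDVRDAASRYAATVATIITPSGHHREQRLGGIHII
WQPTDPNLKANYIYWRPCKYCWSMMCQPHLEGFEATKLWPTCLSFM
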