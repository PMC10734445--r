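; synthetic NIS synthetase exemplar panel (seeded random sequences,
; stand-ins for curated type references; metadata in companion TSV)
>petrobactin_synthetase_like
SIQGSYFMAGCRRKRWQFKVCIPHVPYWKFQAARKRWHDKEIDICVLRDCFKCNSHKYMN
SCHCCARRPYLWHNYHWRWGFQLCYDCCCGPTYDIIHNKEFPRIKCTFIISENFGCFKTV
LIMDWIGSNAECRWVEQHCKGSFNMFRLVLPISTSVKAHLMEPVFTMEWIHKPWLIDRGR
VGFNKGETNQKEPYLSWQFQCWYFVFGLVEIRSVHNEHEHWKWANLFQMKALEVKPWHYH
EIHICRWWNSMSTTWTLDRMVASIHYEFANIYLQYNDIPHIMWEEPECCHCCELTYLYCC
>vibrioferrin_synthetase_like
GLRKNEMPPHQWCEDWHGGQQDWRPAVCQSVTGTTKWWANSDQCIGQCRPKTEIEWTWLD
IFHKRRILKGMIYLMQHNKKMMFVEGDCWWGNIFVTNVTWEMVFPNTSFRKSICTGCLRP
NGWTQHWQDLKQIYEPTTHRANWYHFAQMNLCDHASMTWKPCSNKPWDDNEGQSRWMNWG
SFGCRPLPAQQELWPSGYNRKAEFVVNWQCVCNTWMHPFCRCEDFYRWELNAEHHIKRPF
GAEQPPSTAYIPVDNNCWLHLMNCGFCNVQYADTVRKWVCKQSSDNYHGAQWPDWWRAMT
>rhizoferrin_synthetase_like
RDGYSSCTYEPMCRYKHSKYDQNDPLDPDGYVQDLAKPSFLGIAAAFHLRMCAQMERNCM
AIYGRSSVTIPSEYILSNNGSREAMYETGANSERARPDKRKYQQYVWLTFFNNWTQFHYW
PQKFFAYCYNNFCLFQWMWFMQHALDFKVHNSNMHIGPKEIFFIQLACDWQWNRPTTIDL
ASRLMGNWHKPHINQVIELWRSPAPPLSRVYSEKWQVWKKNDLCYRTDYVMAIMPEPHVC
VLGSSGELSIQECHEAIANIRSCFLYAHRAGLIKIAQSIRQVFLEVGGVADPMRYLYSST
>aerobactin_synthetase_like
ADWKQNCNFMLRCHVQWLVHFVHRRHWGVNSHKYVTVWLYWKSPAIEWMHLMTGFWMQDP
MPHETPIPCMGYFHTVMMATRTWLCNRRRSKVIIWRCLQLGSYWRHWYHWIFVMYQYWVA
SMCEEYAWHWSLDTCKLLHVQDHIHNPLVEHRDTQGILMCSKIEIKMDCNVAIVSLYWLL
DKMWNWIMDKKDQRSTVYGKMEFGFYHGRVTGLVKSFDYEHQCTRLQVLAGKYAYGGFCM
NSEDRLTPKHEDPLPSPVLGGCKAQICRRCKHWLDCVCNHLKGVIHYQSWRGEARWIKII
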