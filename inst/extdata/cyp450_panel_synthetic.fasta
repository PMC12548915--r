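>CYP1A2 synthetic stand-in sequence
MYVGRNTDAILTNAQNTDQQESVAEEPCITMNIRNAVKCQPYVFPIGPVMCLMICWDDFV
TAKTLIFRDCAMPAETCIDRPESKIFLSKRYWSKQEKVCYRKGQQTWLDGWGTVWPYVCT
PPYPIEGINCIESAKFWTFALENHEFARSEMYEKDIHWEPGIDVEVGNSVNDHNQGVSFV
AEYQPEAESQVCDKWMCQQEDCMYYEFGKIYDMHYLQAHNPFRGVNWGIACFYGSDDQKD
RSRYKIESAEDYLAFKYPQRKMTAWKNSFRIMYYMEHSENFFTCEMYATICPGCFICANS
SVHEHGDSSISPEMHCAQIMLEFNSGGHSRITRDMEPGQVENVCMREYDVCVNFPPAFGQ
SQNKWQFRQCHDFYHFIPGVKPVTAGEIFQFEGMYHIVFLPALDLRHISELNRLSAISMG
RRLRVKHRPNLRDIFIYFRWWVHKLQKHWSILCWLACWSQFWKVLLQGKAPSEWAWTCRK
APRQTYWKHHPPRRPSHKCNYCASRWMATVVDRPL
>CYP3A4 synthetic stand-in sequence
VYHLMCNFYPIWVPEYYFIFTATKNKSVGMNCHYEKWAQRCVCIYMIPQMVIFTKNDEGA
RQDKDSLKRPSVNAYKDPELEVTDQNEWVQCQEAIKMTVAYPALTGPERFMGGNPLEWQL
HLRVGHFLILMHHFATWPRHGCPRTMYREFVQMQSGSVWHGNSYYPKLYQIWVDQQLVTC
MPPMHIMMYILSLLQQRVCIQPYWYNHCASRKDSCDVESVIEALSAMSQQGRYNGIDFSI
LDILAHDRNKQDWSGPVVDMAGPVIWCWMMMCRYQYLPYIKNFCFGTNKVAICKLTQCAM
TWKARCVHITHIYCGFESVWDNVASGEWVIEFVNVPWWFEFFHINHAYFPDCSFPVEGSA
CTSFDESGLAWTLVAGADLKRQYCYMHQRKCTHVWQGKDCVHCPADVHPFISAMKDLHSY
TRWEYGCNMSAIHITDGDYFNCRKRVFISYIQGWHCGFAHAVSMWCEWLYCLEDNAQYYT
GMNYPQTYNESMDRTLKMPAEVH
>CYP2C19 synthetic stand-in sequence
EPCEGVALWVEQTWVQKHFLYICEWFNGSPCDQCNGICPCYGSKTQMADPFRDFRWKMCM
IFDVSIWEMQTRIWAKLRDFHSGITQDFFPLQSEPGTHRPGSPWKGTAAMTVMAKELGGV
KDPGWMRDGTIMFLNYADYPMEKVITFQRFGRSAYSYYWECDCQQLEDQGRMFPMIGNIC
HQIWYSHFTVVRCPELDEGLGGIDVNSMQECEFQDDCYNNRGYVQERWQKDSQWCQNECH
ITSAHNIVWHSPVEVIMVVAGTPYVFNRNCKYCDNATNAQSIGLDNLAKALMGHFCCKYG
GNSALFTAGSRAVRAKIRFSWQKVLAVYYLIQVLDVEKMLMYHANWRFPEECQKDYYKQE
CQPDLLFCKWCAIFATLVLHPENTCVYKQMWWLLVVCDRGGPFYSRRSQILIKNQWMRYI
LIKECGMCFHAWHWREHHWDDLYVWIIVNSGNNFCISIHPICKAMGWTFCLTWEWHISAH
QYCQKEDTKE
>CYP2C9 synthetic stand-in sequence
NTCRMTFEWTPKTPHHHGITLYGSEPRNIALFYKHFYAQFNINCWGGPPFKPKDDQFAES
HCEFLVGHTKHFVVWKQGNWRSNASRHGSAWDRENWILHRTYLQSSMPMWNFMWVQEVNK
HPKRVYGNWYNTCMYWCKCDCGGQGDTQYFDFQTGFFSPPVFICVENDWHREPCSQFVPC
MYPNFNNHHEKVFYGYGWAIRITQMGLRLDMYCSREAYPDYSAHYCDRVDWPWYDTQTTL
SFIRAVPRKMYCTKNFSEVQVRLRKLGKSQHHFYPVRKSTPGNISHCFKLYMKDSCSYIC
SVKHTRMYIIGKVHWMTAAVSRMIYHFVVKHQDLMDNSCCEMGYVYDPTLFIKCCNYTGN
CANTCSWSMTYMCEMLSVQQCINMTAYEMCREWGFEAYFNANVCTSPVKPPPDVMHPGRE
QVEVAGEATPKWEHDCKHTRDNSWHTRRSRWTQECESCPHMEHNDEFNPPCVMMAKHIRS
ILAGAYIRFM
>CYP2D6 synthetic stand-in sequence
CETISDEWTLKVTLSLNEPFPASFQRELRNDFSQGVLERHCDCNWVKIEDRPPTCCIPLH
VMYHVMWKHRQCDFMDLNFTWKEMSLMHGRVWLECEPNSFMNSDHGFEAQETHYREILVD
SLFMPQTAAKVKFMKCSMKRVDKKVIDTHHFMVNGWLMGGLRVSHAIARVAPMCHVTLWF
FVYDAKTCCWTDQNGSHQQVYYEHQIADYMDCQNHTRKDLFFGMRIERTLCWLSFMCQNF
ATHDEMFEWDTMQPDYARHGISNHQIVWENMIQTFLPFEILSDTWAIPHFIRMCLLVLKG
VKTLVEPTQHLICGPHPRGYPRFGHYYVVPCFDTMTLLKKTCLVARDCYIEGQLFLDVFT
SIVSHYQMPVWKAGDYAGHTMEMGGNFFLFFTYKCSLSGWPQQAVFAPQEGMNNDQIDFQ
IWQHDSSVLTTREQDHMMADGLTNRIGCIGKLARAYCPGSQWPKDQFNSTFLCSNNIWDQ
ICIIADCCTMWKNTEQG
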