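>RT
LLPCSMFPMTRWTCKIVGMPLSHFDVWIIKTLPDILICTLHCRHLSFEDGPRGKFPLIEGFRAYHPYKKRIFVMWVFHDS
NCFSKYLSRKEGFEQNAANQKCRYQQVTSSPNFDIGFAEMGYLQTNTCRYRNYMGWELITVAYNGHEWCDYEREWKAEKD
PDKKDYIKNIYKARKCEDKHTAHHDDHENCCPRAKKGNKHHDIDIAIAASVEFWNMCLRAPDDMLYACKFFRKHVVSAFP
WVIKEDLITPTQIACLAADMAIMTNQQDTQSYQFDIYNDEIDAGAMIPSDFMCDENPSSSLRQKNTGIDRMDRSIVPNCW
TFTHPPDPCFLGWCIAMVHNIFYYMLDMILFFEVDIEWFIPDRMRVPDSHQPIANVNQVHVVCQRDFQVKKKNQVHWIKP
MYGPPPAYQLILSRANYRTA
>cas1
DKYMYTGGREQHPDWMPIWIFFTAMILVWKRSGYCCGGWMEAYVGMKRKWLYNAFDLAIHTWGLAYDHNCSRTAMISMRV
KCYWGRKLGCPWDKLYSRIQVEARHQTPSVYCMHRTDYPFHLAPRPWSLANPWNCQSPQHYTPECNIASFFISFDFIKII
WNDQKAKDSFYRGHYPVIMHNDKLCRCHPVRKGYFLMIHLPLQFEPEYHWIIWLLMFHFTYYAAAAMRLFKDHYANTNCD
MMFQDFTMSTQVLPIRMGLTCAGNQVITLEICPAWFYEYAKCIIRFLRWMVQWCQGTQFK
>cas2
QYACYVCTAWYVAHWRHPEPDYFMLRDCQDDKIGKDTEKNGQHDSQKENRLENAEGNAVWTIHDQLCQCYVRKLVLDHSG
KDWNKYGAGGHQIEFCSHTGYFGKGGYHWPHDDEGRICLN
>cas6
CGRCYMLPNRLDSVFHAKFKHIKEWHVVMNHTWYCFYYDNRISMWDTSAWFMHDRTYYGFEFEPFVEGRAHEQKCHYHSY
YCYKYNYWICVTGEANVERTPEAIPNKPNQGFHRWWVFGRCELDNKDYQAKIITYDCGADCWYYVAHMPSHETFQWVCAM
NVYEFQSFGQINPLSDEYENEIPKWEWCYCNRWSVLMELAIFYHQTGIETDPDTYSNNSYQRDHAYHVHRQIWRNHAAEK
>cas10
PVGPHQENKGYPCDARWARVSNMTHLHPKYMHYVHWKGLQDTAPSKTQNRDTCHVMCHYVCGTIHQFNRHDRVIQFEQQC
CWWDFGYWESDISHDHFINEHKFTFFLALRRGYVEKVPWYSLEKLGGIRIYPQCLGILSHYGGNGQPGTFVAECMMCFGV
DIIFPIDPIGNLVAAESRSCIFWNGVHTWCGQCAHEQSENWQLFRSKRKPEQHEWELFSQDNPGAFWHWVMREKGNVVEV
LTTLLLFWGSPRHTHDAKRLQHQVGGNNDIIAFTNYKTCDAGKEDVPKDPIVLHGLFEGNFEVGQSSNPSFRMTWASFYT
MTTMFAMLLQKMVFYSGVCTFVWMKRIFVEDFTLEACKGRAFSCWGCIPHHNKWGSWMNCHAGPMFPECVKIGVHNYQWD
LAISDRLWWQCYRYHKLNALPNPILRFMSFTWWWCTTTHESYYKQWAKHRYVACYHFTSNWQSWTRHVSDIHMDKMKKDQ
NELIHTFLWNYHREPIVIHMHEWDWRGGAPQCYDRILSGNAGCKFRPDIMAKSFLQEGGDKCSEHDLGGALYDINMPPYR
YQQRRTHHTAQELVGISWRKWAHRQWQQMRIPTRDGHELQEKFPTAYVFTRASKNSPTYWGVFEKLQFLRVMMTYRMQPC
LCRVKMFQQNWGYCYLIRPWWRIVRCICRPTVWGEWTEKGITHHVATHWACAMDCKYEESTYEWELRMVFIVKCSAQTMM
GCENSNNTYSKDGSDYYLHERDESRRCWVD
>csm2
DVTSQYGPSAEHYEEIHLWNKMRKVNWDTWVDLYYMAPYPEEQYMGMHCFRMGYNKAWFRWMSRSAHFWVCSWTDDGVQL
GKCHDYNEHIETPDYAQHYVEPFFDPWKKQLIIIRQNCEQIYMGRDYKYLVMMLCVSTAE
>csm3
RTCYCYYKPYMTQTDFKCSQYDTYHHTGTWGCWPNRWHHMKHYMYSAPLVQDWSYHRTQMSFAKDNVVCAQTVNKMCFDA
YLLWFEGGHYAIGEGIQKWPHVMYAWSRYHKAEQRFKKVIFIEVGGSALHCAIPQVWPWQEWGDMQELEDHDMIIRLGFM
VFPEQGCTYMATWWTGRSFRTGMQMRHNCHKRSEYFTHMYQQYARADECFFDRQNIWIEPTCKFQAIPGC
>csm4
TGGQHRRTPNLQAHCTHPIEQWTCCDWMMINDYEAWDAQPNSPKKPPQWNEPKRRWAGLRAYPCFIRPVTSGCWQKHQKS
VLQCMWTFFKREVVPIAKLVIPWQKSALEEQIADGNPEHRDVRQWWNSPSKVIHNSLMELTGLTTQCTTKDGTSHWHMHG
YGKAKWKETAQIRSIFFNLDFKTHYPGYYVHRYNCRAWQEGYKPKDCEEDTDGFLQMIYRILHGCMSHWMNLRKTVADIM
RPTTSKVSEMRTEYPILWCAEVYTEHQWWDGFKLKSNIVYANVEHDTKLCERACQPNILV
>csm5
HYYGWHSFEWATKVSWHHTLNNSWWTPKEGCYMARPPHMAMDINWMFAVWAEDMCIYKRCQGNDRVEFDFNVPTYWMSNN
DGYLYSISVPGRARTNQSGINGTMVGSNCEARCFIWQYWERVQRWLMGSVPDVECWCLVGIRMFGPWDEYCLFRKDVKMF
CAGIRFVQTTVWKAQQLIMHYSGQKQPHLCEAAIFVWRQTFLNGCHIQDCLIYQYQWSPIMFDMWHKMKTREFDLTEQGD
PYWCRFWFKTMMLQTCACRKNVILMVWEGEWFRLGDSNFYDYVQVYFEPAYLNGPDQKRSANVDPPANPVLFDMLNDYWN
TYTSPSEPYDHRLPYAHGHMIYFTKFVTDS
>cmr1
AHGAKVMCYLCIYDFWFGPKIVANTQIFMCAYGDHYTPHKWMGVMTTKCNDWNQAKDVTFDDQNVVYFVTGGWTEQVIET
AMFWREDSLCFAPIWVNARPVDQQTYTICNAPASVGHWYKFSFLVCVWLNKWKFTRLENKDWTYLWLVSKIHNRWWREHV
WHMHMRWYCETQTPQGLKLHNNVCLIYKSLVNISQSNMVTAFNSIIDDTMVMIKMKKDFMTNRCMSLPFGQMTSPRGSII
SLHESVRFHDYLTSKWNSGDVWMHTCIQKRPWVLHVQMSMLKGYNKEKEETFLLSGLNDCMAERKCWSSPNNLHEHHQCL
GTCYFWGTSYNARIGKLLCRPRCFPTTGEDKAGIVNANLHEWLYGENQGHMDYCMFCEQKEMFAWFMLNSDWAPPDPKKP
>cmr3
VMKQGSFRKNCSWMNRLKWEWLVFKGIIACRNEQLYYGEGIEFTNPRCHETKQLGYCHNAWQKPLPCWCEMEYWPENEHV
FHAPISMAQKVSIIGDMPWQSTTHLGSNRRNNHHFMVMKQKHQILITPEWTGMRDTECRMERTPKYLSNDIKGEFKDRLF
GSPMWEELDPCPDPHCWTTHSNCVKSGEMFSVRTTFCYNRWIETYEYKWWQSGRQVTWFFIGHVMQKHAQKNWKDYLFKA
MDHSGLVMGDFLGFIMWYFTQRDRSIFCNQDDWRWIRGFRGPKPMNLNFSFYMEKEERMELVRFCCKPDKMIVIWEYRDY
ANRIQYFRVAVSKFVSMPIV
>cmr4
PTMMVGWYITMYFNSRSWAPCTWRKAYLNWIIECTDWMNWRQNVRRFQRKFVVYPNDDAFNSYDFRKVYMKPPVCSGALG
MLAWEQEESEMNQSAYVCQYHHHEFTWWVQMSTEMRMCFSSCNHVVIPPEQMIPLADSQCNYWINHKSHDLTCCYLAEGI
EMVPYRCDIGSDKQDHWCPITTHKSCYTMIMMRWNVPEHNPRGTYWSEGKMIMKEESDVAKMCFFDNPWRESKRMLRGDQ
TGVETEWMTNVCTEQMAHGFFCYIGKVIGAGDSFTRMFQHDALLFEQFELAHRAGIYLSY
>cmr5
KGTAVQDQRGDRIRRGCVSINIIWPKVNHLIDICYCFWANQSTATHCTDRHDNLEDITWGIVMSTDWQTLSRSTDIPMKL
GIWFSWPEVFPEWVHKFRCVCYGLEIQWRLPFEALNPLSITESGANFFMHLQKAGFCEGNCKSCPHHGFI
>cmr6
KEFIWPNRIRNSQHVDDWERWIHYNCLGKMCPRVGWCCQFKSVWLYFFSTWLVKNTCDKQYLMEPDPMRETWRPFATISR
LMKELWKFVLFAGWATKWWSLEQVEDSAIEFIHNVTQLPCQEDLTQNYKACDYDCIQVCIGYEDYIPYLIKIMIPFGINF
NSVYFETYPVSETRNYPIKWNMGYVPWICLTFFMIKSKWSWADRQLQNRFVNLPSCAFYLSHDSKDLYPFSSNVENWLFQ
SLYSFYRHLSPKDVMYNERHWDWALNENISAWKGAINPNE
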