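>TerL1 synthetic reference extein
MREQHYAMRYGYWALFEWVEAYGAEQWNPNQINHQMDPLGMVSLWQTFVKKQKAIKDRFSGPSGSGKTSC
HHVPTQLGYTGWVMQEVVNELMYHLWIWGQVSPTGKCTPNWWDAPENYFDQTNHVRAPPYFPIWEHHQAN
ILLTDEHGRICEIKITHIPTLPVIATHRCTCKRWVVLKNVSSRRMWHQDARLKGIYIWQEQSARGTWTHE
GQCIVKPQNASAEHQQSDAPFIQMHFTLIESIYELVQRICHLPWDNGWKVHNMWRMDSVFFVFMFATTYK
SFPPYILSTCRNEEGNGLYRREEHQQNPATFSFMEVMSRA
>TerL6 synthetic reference extein
MRVKRLTFKFITHLDRVMVMEIREKDSQLDANVNPNVQCCFCWFPDQHACSFTIGASGSGKTCIVFMPVK
VYPALHYGCDSLQGGTMCNHNPPKDPLFVCCCEENPVVKEFIFQYCDGQAASFDYVQKCFVLLTDEPKVS
VLGGHHGCKLKKITCSYHCSFTDSLWKWSVRSHPYNHAFLMPSSGCTWRDTSGCTRGNSAWYLRIPCLCH
PMNYLMGTAPARQSPVGEVMWMRYPHNTINPYTLIEIQTDLWDYCSCIWAGSNDFQVRTRQYNHFHTQQY
SNDFSGNFKKRTGGYLYPKG
>Pham3880 synthetic reference extein
MQDDRRYYFWEYPAWEVWDYSGKQVKKWWDEHCLELVYTRQPQEGHNEETVIKIECCGANFWHDQTQHQC
TSGACRGQQQCCSRHTDGAQCDEKKMWWLDPSCDTATTPDFDLGNGCSGDNHDYLGKDNHVHQCKYDDTW
GSDSDQEPNGLSPPYILTMWYVNPFDCHHKNLEERNATFDSCHSDYGRGDADGMSEGREDAIWYEEMSMF
DCWTLLMNLMRTSCVLIFDVGCPPASLKFDRCCMIGELDT
>RecB synthetic reference extein
MMWTEVQYQYYPPNWRMGSVISAEMRKKWGCIQMVVEMDSGRAPAKARPWFWHHAVPPMICNLVQPMPTG
APAKDDLMPLFWVDNCMRWFYSQTMWFDPPEFNSIHMTRGGVSIKYPYACPDLLCTDYKARVINCEDAHY
CVWFPDMIVYVWWKCHEIYHTQEHASWQMYESVFRFQCGPFGCVGEGRPWECCICAMPMTWHQTEAPTEE
GHRKNARQYVFRRIPVKNRCTIRVNCWCQMCESYLALCPYYAADNFKYVPTDSVRWTMHWQIRCNMCYCG
>RDF synthetic reference extein
MPYESCGSAASLVALYGKSALNWIAAMYPDHKGMWYKYLVHYETTYVNIGEMIVFCASAKFSIVAPALPA
VSLCEMERTRKENVMVMDYTGDLHGCNLPAFEMGNIRLILWKVPDWPWNDKIEKPMYMKVPGQPTVSRAL
FPHCPICCPVCVGNWAVAVWKDKEPYKNFNTMWQCRGPSSAGFFDTWIMHIMIGCTVKFD
>TOPRIM synthetic reference extein
MNESGLTYLEFSVVYNMTNYDFHFNVFYHTTLCRANHDWRAIAMNHYWWSAMHSKCWDAWSMYQNDVIFA
DLQCVNKFDPMSQSHYENIWMLWDHIKEQCCGHHILEPGWDADECGSHKRTIEEREQTDFERRVTRDQIF
FHEQPDSANLNWRIKGMIQMKCTNIIMFGQSKTNKIECFITVASVWRMVMFISKQAREFVALWLNPYPKE
AMYNDNEAIVDEDYKRHCKKYFAHQPFIKNEEMLTHRAKFKLAAQFMTAP
>NT synthetic reference extein
MNNHKGVHAGKPDKIDLYNKRSYTHEPTFRWSRKSEEAGWLGISHSKRRLDARENLDSEPASMWTSWDID
SHHFRQTQAAQHCEATWLCSLHTDHCRHDHGGSCLRENVKWNSKMNLVTGDTNPTEISERNLLNYVWMKP
GSPEYGVATPNVPAHTKWNHSCRFDELHIFMREHSVDWNECREACVHYPWYIYTFYPHDKYPTVFIIAYE
EGGVHVEKAFICTLNEAATDPANAQMECVA
>DNMT1 synthetic reference extein
MLQWNRLAMHCSLQRQLKCHIHHWLCHFCDALPTVVQFHYLRMDQTAKHWLCCNFVLMQEMTPNNMWLRV
KAHPCDWCMEMNIMLTMDQIEFVENPPYCGDGYIETADYMMYCWEPMEGLVVTGILKYFHEFTVYTRPVM
QASLICWMAPFGWTDVLCMHGYAWNQQGRTMECESKWRSRNKKEHSECKGIFDRCRIDFAYTCNIHWVWM
VSQYYQWKKWWLMHDLEHQATPWDANQFNDGQKHQPVKTHEQSFSIQEFA
>DNMT2 synthetic reference extein
MMIQFPSGLNKSIKNVGIRAPHRMQSGVVYGEDCEMWISKPSKQWRHVLHMTQRPQLAANEGMQWLEPHP
FTWYCTDCKFWQYTHYDEPDPPYCNGADNHQSWTNMKFPWRTKPHPRWYPHKKAYHWVTTGFHEVCNQKC
FMYFMWQYEMALKGRDVRYRKRMPNKEICTTQHTFWEVCKESHNFRRTDWRDDHGFEPFTWGPIETLERV
LVMPLPWMLVYMQGCDKLEPWPHDGIMETC
>PORT synthetic reference extein
MWEAAHWAEDVRRFHMKMWSADAASMQDWFKKFMNWPDEKVFELTMENDIVMHYINTLNEPGDFFIRAPR
YHAYHPYCYVFTAMVRRVHWGANIPTRMYNMNKDHTPIESAEYTFSWCIWNMCEKEMFYADWAQSGPLFC
DEWWCVQSSAQETCGLRDLPHDKQTHTIKCESYNYTETSTGNDCIKKHAWMPDCVHIFTIYNLNGEAYHW
DEVAWEQCKHDGQHPVWEHDFRGRKHQDYVIYWAKTDLSTQAQPWMGTYYDRPDQYCNDRDHIYYAQSTL
CNKKQKYQEKTPVAWSIHCY
>HEL synthetic reference extein
MHYYCKLQDVKNCTHDGWENHYMWFGWNPWQMQQEEFMVSYFMCGPRNAMCISWKMITCWLKMLYSQKPE
GSGKSTLCACNFASFVTGDEEIQMWPCEHRLLTTYPCSLMMWHGVWPGPSPQRYHSVLMSEVKAMFEEEG
RYWSCGPAMEYAPWFIARVDFQKATCKNCFKMKWDFGEVLWLCSTFGLQGPMFNGEYEPGGNILKCCHLS
AENLDVVDYSMRVLCTMGKWAFDLSAVQGGEKQCPCADFSHCAPWNHAFCIGTCMEAPRGVVKPKFGMDK
TTCKMVGIIASMVDMIAFDLGLCFKKQDPM
>TdS synthetic reference extein
MPVALSWYNIIPFQGVKTLLVWGRMHWKGLDTCKANKMTWRWRCEDYWDNSCNSVMCMPTADTQLGRKEN
MGVVTTYDPDSITTTFQMTDRNRFTDQATIMSLHKRHYSCEAGNYDWLWIVVYTIVDIFYQNDEERDQIS
FQREQTEQRILNTDMDVTGQCILAGCRYHNEHPMMMVYWGVHHQHTKSMPCCDMHEPRKIKISVHHCIWY
NMHFGENARERDCYWEGKKTEPYYYRDKSFEGGGIRLVMF
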