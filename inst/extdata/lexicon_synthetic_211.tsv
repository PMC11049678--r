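appeal	^pil
box	baks
boost	bust
duty	duti
greet	grit
least	list
school	skul
shield	Sild
screw	skru
ugly	^gli
plug	pl^g
blush	bl^S
w001	did
w002	gid
w003	didutka
w004	dibdi
w005	gidpla
w006	tid
w007	aid
w008	Sid
w009	gi^dslt
w010	gilsgSls
w011	gi
w012	lid
w013	gikt
w014	didp
w015	rid
w016	d^dpSltid
w017	pid
w018	gikikidup
w019	lip^
w020	gigbak
w021	gipu
w022	litu
w023	uid
w024	di
w025	gik^
w026	Sgiuilrg
w027	si
w028	sirS
w029	Sib^rd
w030	sid
w031	d^
w032	gibgltd
w033	ui
w034	liurp
w035	sirap^au^
w036	li^krauga
w037	aiu
w038	gil
w039	sisbapt^t
w040	uiaS
w041	gidi
w042	rituS
w043	pidrbrtug
w044	dbagilk^g
w045	uridt^
w046	Siu
w047	gibt^
w048	gitrgsis
w049	dig
w050	usSiuS
w051	bi
w052	sig
w053	lib
w054	gidlkS
w055	akgi
w056	ailslb
w057	arlidg
w058	ti
w059	Sig
w060	pig
w061	ri
w062	ditid
w063	piu
w064	bid
w065	girprSs^S
w066	pi^ub
w067	uiuak
w068	uial
w069	usdgpdk
w070	^i
w071	piabt^a
w072	bibdsu^
w073	piup
w074	disSbs
w075	git^
w076	d^b^bpbd
w077	gili
w078	gipS^ptg^
w079	aipt
w080	uig
w081	db
w082	su^aid
w083	giudsd
w084	aitirigu
w085	giasd^l
w086	dirtuiS
w087	dgil
w088	aig
w089	tig
w090	bi^p
w091	uik
w092	l^kbi
w093	gidrSur
w094	Sgtak
w095	uidgrdSsa
w096	sil
w097	gi^uSus
w098	sik
w099	biSlrSa
w100	usStk
w101	big
w102	ailu^s^
w103	pil
w104	gigaSi
w105	gig
w106	Si
w107	galidlsk
w108	dgbgi
w109	risikSik
w110	alibrsibt
w111	uika
w112	si^uat^
w113	ldigtgsgs
w114	gibirduk
w115	dilgSk
w116	gidt
w117	sit
w118	rikbr
w119	usi
w120	kpiu
w121	lSusiaSu
w122	SgatSbag
w123	kp
w124	tidpSsi
w125	buid
w126	ptig
w127	l^ba
w128	dib^ulpk
w129	gipdibgSg
w130	kiSig^p
w131	tiSbi
w132	rit^ruikd
w133	ragidiSu
w134	^iu
w135	tilgrk
w136	dis
w137	gitpb^gs
w138	aipid
w139	stlglid^l
w140	tiutrbk
w141	gigpr
w142	sbdb
w143	uisb
w144	raukgd
w145	aibkrpdrt
w146	bis
w147	Sig^
w148	kil
w149	alib
w150	Sirtsgsr
w151	liub
w152	p^bis
w153	d^psl
w154	ki
w155	dbu
w156	pdibuasa
w157	d^pibtStg
w158	idbuprliS
w159	didptd
w160	sililala
w161	bigplSs
w162	bdtpaid
w163	gp
w164	riasik
w165	gisubgp^
w166	bigtui
w167	rigarl
w168	til
w169	Sp
w170	pi
w171	lib^
w172	sb
w173	dik
w174	^itd
w175	bSksidp
w176	birsbl
w177	tiS
w178	kagi^kSl
w179	bisl^bS
w180	giS
w181	brSi
w182	tip
w183	isigsgkpS
w184	dp
w185	Sisigbi
w186	rik
w187	uiu
w188	ai
w189	bik
w190	gik
w191	dit^abipd
w192	uspu
w193	pili
w194	aiktak
w195	gibab
w196	riu
w197	giSa
w198	uids
w199	uispkl^p
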