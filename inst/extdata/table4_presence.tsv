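species	infraorder	A2α1	A2β	A24α	A24β1	A24β2	A24β3	A34α1	A34α2	A34β1	A34β2	A34β3
A. japonicus	Brachyura	0	0	0	0	0	0	1	1	0	0	0
C. borealis	Brachyura	1	0	1	1	0	0	0	0	0	1	0
C. maenas	Brachyura	1	1	1	1	1	0	0	0	1	1	1
C. sapidus	Brachyura	0	1	0	1	1	0	0	0	0	1	0
E. sinensis	Brachyura	0	0	1	1	0	0	1	1	1	1	0
G. lateralis	Brachyura	1	0	1	1	1	0	0	1	1	1	0
L. pugilator	Brachyura	0	0	0	0	0	0	0	0	1	1	0
P. trituberculatus	Brachyura	0	0	0	0	0	0	1	1	1	1	1
S. olivacea	Brachyura	0	0	0	0	0	0	0	0	1	0	0
S. paramamosain	Brachyura	0	0	1	0	0	0	1	0	1	1	1
C. quadricarinatus	Astacidea	1	0	1	0	0	0	0	1	1	0	0
H. americanus	Astacidea	0	0	1	0	0	1	0	0	1	0	0
N. norvegicus	Astacidea	0	0	1	0	0	0	1	0	1	0	0
P. clarkii	Astacidea	1	1	1	1	1	0	1	1	1	0	1
C. antilillensis	Anomura	0	0	1	0	0	0	0	0	1	0	0
C. tricolor	Anomura	0	1	1	0	0	0	0	0	0	0	0
C. vittatus	Anomura	1	0	1	0	0	0	0	0	1	0	0
C. laevimanus	Anomura	0	0	0	0	0	0	0	1	1	0	0
E. talpoidea	Anomura	0	1	0	0	0	0	0	0	1	0	0
M. microphthalma	Anomura	0	0	1	0	0	0	0	0	0	0	0
S. formosus	Anomura	0	0	1	1	0	0	0	0	0	0	0
L. vannamei	Penaeoidea	0	0	0	0	0	0	1	1	0	0	0
P. monodon	Penaeoidea	0	0	1	0	0	0	1	1	1	0	0
A. cf. viridari	Caridea	0	0	1	0	1	1	0	0	0	0	1
A. stylorostratis	Caridea	0	0	0	0	0	0	0	0	1	0	0
B. texana	Caridea	0	0	1	0	0	0	0	0	1	0	0
G. aculeata	Caridea	1	0	0	0	0	0	0	0	1	0	0
L. amboinensis	Caridea	0	0	0	0	1	0	0	0	1	0	0
M. rosenbergii	Caridea	0	0	1	0	0	0	0	0	1	0	0
N. denticulata	Caridea	0	0	0	0	0	0	0	1	0	0	0
O. spinosus	Caridea	0	0	0	0	0	0	0	0	1	0	0
P. australiensis	Caridea	0	1	0	0	0	0	0	1	1	0	1
P. richardi	Caridea	0	0	0	0	1	1	0	0	0	0	1
S. debilis	Caridea	0	0	1	0	0	0	0	0	1	0	0
P. argus	Palinuroidea	0	1	1	1	0	0	0	0	1	0	0
P. ornatus	Palinuroidea	0	0	1	0	0	0	0	1	1	0	0
S. verreauxi	Palinuroidea	0	0	1	0	0	0	1	0	1	0	0
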