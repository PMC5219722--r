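# Builtin restriction enzyme table: common commercially available enzymes.
# Format: Name<whitespace>Recognition, IUPAC ambiguity codes allowed,
# recognition length 4-8 nt. '#' starts a comment; blank lines ignored.

# 6-bp palindromic
AatII   GACGTC
AfeI    AGCGCT
AflII   CTTAAG
AgeI    ACCGGT
ApaI    GGGCCC
AseI    ATTAAT
AvrII   CCTAGG
BamHI   GGATCC
BglII   AGATCT
BspHI   TCATGA
BsrGI   TGTACA
BstBI   TTCGAA
ClaI    ATCGAT
DraI    TTTAAA
EcoRI   GAATTC
EcoRV   GATATC
FspI    TGCGCA
HindIII AAGCTT
HpaI    GTTAAC
KpnI    GGTACC
MluI    ACGCGT
NaeI    GCCGGC
NcoI    CCATGG
NdeI    CATATG
NheI    GCTAGC
NsiI    ATGCAT
PstI    CTGCAG
PvuI    CGATCG
PvuII   CAGCTG
SacI    GAGCTC
SacII   CCGCGG
SalI    GTCGAC
ScaI    AGTACT
SmaI    CCCGGG
SnaBI   TACGTA
SpeI    ACTAGT
SphI    GCATGC
SspI    AATATT
StuI    AGGCCT
XbaI    TCTAGA
XhoI    CTCGAG

# 8-bp palindromic
AscI    GGCGCGCC
FseI    GGCCGGCC
NotI    GCGGCCGC
PacI    TTAATTAA
PmeI    GTTTAAAC
SbfI    CCTGCAGG

# 4-bp palindromic
AluI    AGCT
HaeIII  GGCC
HpaII   CCGG
MboI    GATC
MseI    TTAA
RsaI    GTAC
Sau3AI  GATC
TaqI    TCGA

# degenerate recognition sequences
AccI    GTMKAC
AflIII  ACRYGT
ApoI    RAATTY
AvaI    CYCGRG
AvaII   GGWCC
BanI    GGYRCC
BsaWI   WCCGGW
BstYI   RGATCY
DdeI    CTNAG
HincII  GTYRAC
HinfI   GANTC
NspI    RCATGY
Sau96I  GGNCC
StyI    CCWWGG

# non-palindromic (scanned on both strands)
BbsI    GAAGAC
BciVI   GTATCC
BmrI    ACTGGG
BsaI    GGTCTC
BsmBI   CGTCTC
BspMI   ACCTGC
EarI    CTCTTC
FokI    GGATG
HgaI    GACGC
MlyI    GAGTC
SapI    GCTCTTC
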