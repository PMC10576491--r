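# Synonym table mapping common GenBank qualifier spellings to the
# canonical gene vocabulary. Keys are matched case-insensitively.
# Unknown labels are reported as warnings by the reader, never errors.
ND1: nad1
ND2: nad2
ND3: nad3
ND4: nad4
ND4L: nad4L
ND5: nad5
ND6: nad6
NADH1: nad1
NADH2: nad2
NADH dehydrogenase subunit 1: nad1
NADH dehydrogenase subunit 2: nad2
NADH dehydrogenase subunit 3: nad3
NADH dehydrogenase subunit 4: nad4
NADH dehydrogenase subunit 4L: nad4L
NADH dehydrogenase subunit 5: nad5
NADH dehydrogenase subunit 6: nad6
COI: cox1
COII: cox2
COIII: cox3
CO1: cox1
CO2: cox2
CO3: cox3
COX1: cox1
COX2: cox2
COX3: cox3
cytochrome c oxidase subunit I: cox1
cytochrome c oxidase subunit II: cox2
cytochrome c oxidase subunit III: cox3
CYTB: cytb
COB: cytb
CYB: cytb
cytochrome b: cytb
ATP6: atp6
ATP8: atp8
ATPase6: atp6
ATPase8: atp8
ATP synthase F0 subunit 6: atp6
ATP synthase F0 subunit 8: atp8
12S: rrnS
12S rRNA: rrnS
12S ribosomal RNA: rrnS
s-rRNA: rrnS
small subunit ribosomal RNA: rrnS
16S: rrnL
16S rRNA: rrnL
16S ribosomal RNA: rrnL
l-rRNA: rrnL
large subunit ribosomal RNA: rrnL
tRNA-Phe: trnF
tRNA-Val: trnV
tRNA-Ile: trnI
tRNA-Gln: trnQ
tRNA-Met: trnM
tRNA-Trp: trnW
tRNA-Ala: trnA
tRNA-Asn: trnN
tRNA-Cys: trnC
tRNA-Tyr: trnY
tRNA-Asp: trnD
tRNA-Lys: trnK
tRNA-Gly: trnG
tRNA-Arg: trnR
tRNA-His: trnH
tRNA-Glu: trnE
tRNA-Thr: trnT
tRNA-Pro: trnP
tRNA-Leu (UUR): "trnL(UUR)"
tRNA-Leu (CUN): "trnL(CUN)"
tRNA-Ser (UCN): "trnS(UCN)"
tRNA-Ser (AGY): "trnS(AGY)"
trnL-UUR: "trnL(UUR)"
trnL-CUN: "trnL(CUN)"
trnS-UCN: "trnS(UCN)"
trnS-AGY: "trnS(AGY)"
trnL1: "trnL(UUR)"
trnL2: "trnL(CUN)"
trnS1: "trnS(AGY)"
trnS2: "trnS(UCN)"
D-loop: CR1
control region: CR1
control region 1: CR1
control region 2: CR2
CR: CR1
remnant CR2: CR2
remnant control region: CR2
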