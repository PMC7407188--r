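#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
S_100                PF01023.21    46 sp|P04271|S100B_HUMAN -             92   2.1e-22   79.0   0.1   1   1   1.2e-26   2.5e-22   78.8   0.1     1    45     3    46     4    46 0.97 S-100/ICaBP type calcium binding domain
EF-hand_1            PF00036.34    29 sp|P04271|S100B_HUMAN -             92   1.3e-05   25.4   0.2   1   1   1.6e-09   3.1e-05   24.2   0.2     1    29    50    78    53    81 0.95 EF hand
#
# Program:         hmmscan
# Version:         3.4 (Aug 2023)
# Pipeline mode:   SCAN
# Query file:      P04271.fasta
# Target file:     Pfam-A.hmm
# [ok]
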