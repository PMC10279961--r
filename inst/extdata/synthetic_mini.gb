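LOCUS       SYNPL001              280 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  Synthetic miniature plastome-like record for parser tests.
ACCESSION   SYNPL001
FEATURES             Location/Qualifiers
     source          1..280
                     /organism="synthetic construct"
     gene            1..60
                     /gene="psbA"
     gene            61..120
                     /gene="rbcL"
     tRNA            121..150
                     /gene="trnH-GUG"
     rRNA            151..200
                     /gene="rrn16"
     gene            complement(221..280)
                     /gene="psbA"
ORIGIN
        1 aaaactccat gtgtaactcc ggaagtagaa tcttgcactc ggcctttcca tatctcgtga
       61 accccctgca cgccctaaag tacaattagg atattcatcc ctacactgta tatgccgaac
      121 gttctaataa acgacttagc aacaagtcgc ctagaaaggt accgctggca tatcacgcct
      181 cccgcttgcc gtcttcaact tcatgaccct cgtgcatcac aaagcctcaa gccggagtct
      241 aggctttgaa acagctgaat aaatcgtgtg aatacgtgag
//
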