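# Mapped-read accounting rows from published bacterial rRNA-depletion
# experiments (RNA-Seq, Term-Seq and ribosome profiling): total reads mapped
# on the genome, reads mapped on each rRNA class, the rRNA subtotal and the
# percentage as printed. Rows with known_discrepancy=TRUE print a percentage
# exactly 0.01 above the value recomputed from their own count columns.
table,organism,method,note,mapped_reads,s5,s16,s23,subtotal,pct_printed,known_discrepancy
1,Escherichia coli MG1655,None,untreated,3310864,119,1744649,1507768,3252536,98.24,FALSE
1,Escherichia coli MG1655,None,untreated,3059840,61,1521945,1480521,3002527,98.13,FALSE
1,Escherichia coli MG1655,MICROBExpress,,2551754,307,896617,1301681,2198605,86.16,FALSE
1,Escherichia coli MG1655,MICROBExpress,,2184739,182,719517,1127048,1846747,84.53,FALSE
1,Escherichia coli MG1655,Ribo-Zero,,6948099,4,900,2979,3883,0.06,FALSE
1,Escherichia coli MG1655,Ribo-Zero,,10630331,7,670,2242,2919,0.03,FALSE
1,Escherichia coli MG1655,RiboErase,,6289463,3297,35305,75359,113961,1.81,FALSE
1,Escherichia coli MG1655,RiboErase,,6703891,3224,87175,197847,288246,4.30,FALSE
1,Escherichia coli MG1655,RNase H depletion,Standard method (I1.0-ArOP5-T65),5832388,25,22889,62093,85007,1.46,FALSE
1,Escherichia coli MG1655,RNase H depletion,Standard method (I1.0-ArOP5-T65),6107778,37,129249,275698,404984,6.63,FALSE
1,Escherichia coli MG1655,RNase H depletion,without enzyme (mock),1949301,23,832406,1062779,1895208,97.23,FALSE
1,Escherichia coli MG1655,RNase H depletion,without enzyme (mock),1589651,18,688612,859085,1547715,97.36,FALSE
1,Escherichia coli MG1655,RNase H depletion,I0.5-ArOP5-T65,3398659,2310,106652,134399,243361,7.16,FALSE
1,Escherichia coli MG1655,RNase H depletion,I0.5-ArOP5-T65,2162423,2150,46380,56302,104832,4.85,FALSE
1,Escherichia coli MG1655,RNase H depletion,I1.0-ArOP10-T65,1239187,659,8236,11761,20656,1.67,FALSE
1,Escherichia coli MG1655,RNase H depletion,I0.5-ArOP10-T65,2304011,1367,30127,39531,71025,3.08,FALSE
1,Escherichia coli MG1655,RNase H depletion,I1.0-ArOP5-T65,1274201,764,33805,43352,77921,6.12,FALSE
1,Escherichia coli MG1655,RNase H depletion,I0.5-ArOP5-T45,2012043,584,318343,238087,557014,27.68,FALSE
1,Escherichia coli MG1655,RNase H depletion,Standard method,12984470,25927,79291,66971,172189,1.34,TRUE
1,Escherichia coli MG1655,RNase H depletion,Standard method,12019200,19354,108427,144759,272540,2.28,TRUE
1,Escherichia coli MG1655,RNase H depletion,SPRI + C3-spacer 55-probe set,23361967,47624,42410,55477,145511,0.63,TRUE
1,Escherichia coli MG1655,RNase H depletion,SPRI + C3-spacer 55-probe set,21201607,44499,94442,205618,344559,1.64,TRUE
1,Klebsiella oxytoca KCTC1686,RNase H depletion,anti-E. coli probe set,3784202,3331,42380,49299,95010,2.51,FALSE
1,Klebsiella oxytoca KCTC1686,RNase H depletion,anti-E. coli probe set,2029169,2222,12972,12332,27526,1.36,FALSE
2,Pseudomonas aeruginosa,RNase H depletion,5 U enzyme,26174448,4500,312841,1164705,1482046,5.66,FALSE
2,Pseudomonas aeruginosa,RNase H depletion,5 U enzyme,23088094,3399,56816,479347,539562,2.34,FALSE
2,Pseudomonas aeruginosa,RNase H depletion,10 U enzyme,28748624,3954,167246,737542,908742,3.16,FALSE
2,Pseudomonas aeruginosa,RNase H depletion,10 U enzyme,29991165,3557,13083,452044,468684,1.56,FALSE
2,Pseudomonas aeruginosa,RNase H depletion,with pre-rRNA probes,19868429,1106,4442,46126,51674,0.26,FALSE
2,Pseudomonas aeruginosa,RNase H depletion,with pre-rRNA probes,21443360,889,41453,125739,168081,0.78,FALSE
2,Staphylococcus aureus,RNase H depletion,Medium (CAMHB),16321596,9,19418,35296,54723,0.34,FALSE
2,Staphylococcus aureus,RNase H depletion,Medium (CAMHB),16852709,112,105020,185302,290434,1.72,FALSE
2,Staphylococcus aureus,RNase H depletion,Medium (RPMI),14734909,2,694,1026,1722,0.01,FALSE
2,Staphylococcus aureus,RNase H depletion,Medium (RPMI),15889282,2,1592,3470,5064,0.03,FALSE
2,Eubacterium limosum,RNase H depletion,Standard method,8079397,563,63851,117606,182020,2.25,FALSE
2,Eubacterium limosum,RNase H depletion,Standard method,9107085,479,125218,229290,354987,3.90,FALSE
2,Bacteroides thetaiotaomicron,RNase H depletion,probe set 1,2118423,0,275845,406929,682774,32.23,FALSE
2,Bacteroides thetaiotaomicron,RNase H depletion,probe set 1,2528261,0,221023,339672,560695,22.18,FALSE
2,Bacteroides thetaiotaomicron,RNase H depletion,probe set 2,7480373,0,746822,589762,1336584,17.87,FALSE
2,Bacteroides thetaiotaomicron,RNase H depletion,probe set 2,9225721,0,934332,705684,1640016,17.78,FALSE
2,Bacteroides thetaiotaomicron,RNase H depletion,probe set 2 at 58 C,1952549,0,75339,59576,134915,6.91,FALSE
2,Bacteroides thetaiotaomicron,RNase H depletion,probe set 2 at 58 C,1136665,0,134350,124706,259056,22.79,FALSE
3,Streptomyces coelicolor Term-Seq,RNase H depletion,Standard method,6435085,80,9911,18072,28063,0.44,FALSE
3,Streptomyces coelicolor Term-Seq,RNase H depletion,Standard method,3229425,27,2724,6654,9405,0.29,FALSE
3,Escherichia coli ribosome profiling,Ribo-Zero,,72406373,8511,28603979,27456111,56068601,77.44,FALSE
3,Escherichia coli ribosome profiling,Ribo-Zero,,100774910,10569,31910262,40093315,72014146,71.46,FALSE
3,Escherichia coli ribosome profiling,Ribo-Zero,,48475872,8405,11149390,23766472,34924267,72.04,FALSE
3,Escherichia coli ribosome profiling,RNase H depletion,Standard method,2056321,75394,1454309,406072,1935775,94.14,FALSE
3,Escherichia coli ribosome profiling,RNase H depletion,Standard method,3207956,52944,2725659,335259,3113862,97.07,FALSE
3,Escherichia coli ribosome profiling,RNase H depletion,plus additional set 1,1231074,3635,182472,689857,875964,71.15,FALSE
3,Escherichia coli ribosome profiling,RNase H depletion,plus additional set 1,2206290,6101,260871,1422499,1689471,76.58,FALSE
3,Escherichia coli ribosome profiling,RNase H depletion,plus additional sets 1 and 2,8941114,45608,3214429,3159559,6419596,71.80,FALSE
3,Escherichia coli ribosome profiling,RNase H depletion,plus additional sets 1 and 2,3185119,13277,1109650,1019660,2142587,67.27,FALSE
3,Escherichia coli ribosome profiling,RNase H depletion,plus additional sets 1 and 2,2214451,10464,603139,857434,1471037,66.43,FALSE
3,Escherichia coli ribosome profiling,RNase H depletion,plus additional sets 1 and 2,2135544,16454,678992,908681,1604127,75.12,FALSE
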