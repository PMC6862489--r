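generation,trait,classes,observed,expected,reported_chi_sq,note
F2,grain (diameter classes),large|small,134|52,ratio:3|1,0.87,
F3 lines,grain (line fixation),large_homozygous|heterozygous|small_homozygous,10|32|8,ratio:1|2|1,4.08,reported df = 1; the reported P range matches df = 2
BC1F2,grain (area classes),large|small_and_medium,10|32,ratio:1|3,0.03,
BC2F2,grain (area classes),large|medium|small,17|39|14,ratio:1|2|1,1.17,
BC3F2,grain (area classes),large|medium|small,15|13|7,ratio:1|2|1,5.97,
BC4F2,grain (area classes),large|medium|small,8|18|10,ratio:1|2|1,0.20,known discrepancy: recomputes to 0.22 from the printed counts
BC1F2 d60 scheme,culm class,semidwarf|partially_sterile|long_culm,11|26|75,model:culm,0.22,
BC2F2 d60 scheme,grain (area classes),large|medium|small,3|14|7,ratio:1|2|1,2.00,
BC3F2 d60 scheme,grain (area classes),large|medium|small,20|55|19,ratio:1|2|1,2.74,
BC4F2 d60 scheme,culm class,semidwarf|partially_sterile|long_culm,17|36|104,model:culm,0.01,known discrepancy: recomputes to 0.05 from the printed counts
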