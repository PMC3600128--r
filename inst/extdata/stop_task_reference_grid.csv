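measure,sex,age,trait,predicted,ci_low,ci_high
ssrt,female,6,-54,398,385,412
ssrt,female,6,54,536,516,557
ssrt,female,18,-54,177,170,183
ssrt,female,18,54,238,229,247
ssrt,male,6,-54,371,359,384
ssrt,male,6,54,500,483,518
ssrt,male,18,-54,177,170,185
ssrt,male,18,54,239,228,249
gort,female,6,-54,735,723,747
gort,female,6,54,765,752,779
gort,female,18,-54,521,512,530
gort,female,18,54,542,532,552
gort,male,6,-54,693,682,705
gort,male,6,54,722,710,734
gort,male,18,-54,528,517,539
gort,male,18,54,549,537,561
gortsd,female,6,-54,205,200,210
gortsd,female,6,54,256,249,264
gortsd,female,18,-54,118,115,121
gortsd,female,18,54,147,143,152
gortsd,male,6,-54,188,183,193
gortsd,male,6,54,235,229,241
gortsd,male,18,-54,119,115,122
gortsd,male,18,54,148,143,153
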