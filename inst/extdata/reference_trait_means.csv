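genotype,treatment,trait,mean
TDr1499,non-F,dry_shoot_g,76.9
TDr1499,+F,dry_shoot_g,130.5
TDr1649,non-F,dry_shoot_g,64.5
TDr1649,+F,dry_shoot_g,108.1
TDr1899,non-F,dry_shoot_g,45.3
TDr1899,+F,dry_shoot_g,60.7
TDr2029,non-F,dry_shoot_g,48.3
TDr2029,+F,dry_shoot_g,56.4
TDr2484,non-F,dry_shoot_g,48.6
TDr2484,+F,dry_shoot_g,63.7
TDr2948,non-F,dry_shoot_g,57.8
TDr2948,+F,dry_shoot_g,78.3
TDr1499,non-F,dry_tuber_g,235.5
TDr1499,+F,dry_tuber_g,489.9
TDr1649,non-F,dry_tuber_g,235.8
TDr1649,+F,dry_tuber_g,433.3
TDr1899,non-F,dry_tuber_g,155.8
TDr1899,+F,dry_tuber_g,239.0
TDr2029,non-F,dry_tuber_g,260.0
TDr2029,+F,dry_tuber_g,313.8
TDr2484,non-F,dry_tuber_g,200.0
TDr2484,+F,dry_tuber_g,262.5
TDr2948,non-F,dry_tuber_g,260.7
TDr2948,+F,dry_tuber_g,370.3
TDr1499,non-F,tuber_dm_pct,27.8
TDr1499,+F,tuber_dm_pct,28.6
TDr1649,non-F,tuber_dm_pct,31.2
TDr1649,+F,tuber_dm_pct,34.1
TDr1899,non-F,tuber_dm_pct,32.5
TDr1899,+F,tuber_dm_pct,33.1
TDr2029,non-F,tuber_dm_pct,31.0
TDr2029,+F,tuber_dm_pct,29.3
TDr2484,non-F,tuber_dm_pct,25.5
TDr2484,+F,tuber_dm_pct,27.0
TDr2948,non-F,tuber_dm_pct,28.2
TDr2948,+F,tuber_dm_pct,28.7
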