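text,dn_min,dn_max,df_min,df_max,di_min,di_max,unit,flags
take 2 tablets 4 times a day,2,2,4,4,1,1,tablet,
2 tabs qid,2,2,4,4,1,1,tablet,
a half to one tablet to 2 three times a day when required,0.5,2,0,3,1,1,tablet,as_required
10 mg to be taken weekly,10,10,1,1,7,7,mg,
2 with each meal,2,2,3,3,1,1,?,
take 2.5 ml twice a day,2.5,2.5,2,2,1,1,ml,
half a tablet twice a day when required,0.5,0.5,0,2,1,1,tablet,as_required
2 puffs 6 hrly prn,2,2,0,4,1,1,puff,as_required
1 to 3 every day,1,3,1,1,1,1,?,
one or two to be taken every 4 to 6 hours,1,2,4,6,1,1,?,
take as directed,1,?,?,?,1,?,,as_directed
apply as needed,1,1,0,?,1,?,,as_required
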