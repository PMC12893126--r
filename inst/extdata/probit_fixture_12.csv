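subject_id,eye,site,dose,dose_unit,outcome,session_id
SYN01,OD,1,60,J/cm2,0,S01
SYN01,OD,2,66,J/cm2,0,S01
SYN01,OD,3,72.5,J/cm2,0,S01
SYN01,OD,4,79.7,J/cm2,0,S01
SYN01,OD,5,87.6,J/cm2,0,S01
SYN01,OD,6,96.3,J/cm2,1,S01
SYN02,OD,1,105.9,J/cm2,1,S02
SYN02,OD,2,116.4,J/cm2,1,S02
SYN02,OD,3,128,J/cm2,0,S02
SYN02,OD,4,140.7,J/cm2,1,S02
SYN02,OD,5,154.6,J/cm2,1,S02
SYN02,OD,6,170,J/cm2,1,S02
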