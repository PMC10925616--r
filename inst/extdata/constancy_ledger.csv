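"timestamp","activity_mCi","device_id","calculated_mCi"
"10/24/18 11:00",206,"Atom Lab 1",199.97
"10/25/18 10:00",186.5,"Atom Lab 1",180.95
"10/26/18 10:00",168.5,"Atom Lab 1",163.03
"10/30/18 10:00",110.9,"Atom Lab 1",107.43
"10/31/18 11:20",99.3,"Atom Lab 1",96.37
"10/24/18 11:00",208,"Atom Lab 2",199.97
"10/25/18 10:00",187.9,"Atom Lab 2",180.95
"10/26/18 10:00",170.3,"Atom Lab 2",163.03
"10/30/18 10:00",112.2,"Atom Lab 2",107.43
"10/31/18 11:20",100.6,"Atom Lab 2",96.37
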