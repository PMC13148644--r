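"patient_id","freq_hz","threshold_db_hl","age","sex","race","ethnicity"
"P001",250,95.9218351382796,13,"male","other","non_hispanic"
"P001",500,105.861636314759,13,"male","other","non_hispanic"
"P001",1000,88.2048367628021,13,"male","other","non_hispanic"
"P001",2000,93.8977166745327,13,"male","other","non_hispanic"
"P001",4000,120,13,"male","other","non_hispanic"
"P001",8000,120,13,"male","other","non_hispanic"
"P002",250,43.7650442984909,5,"male","black","non_hispanic"
"P002",500,63.2679717235671,5,"male","black","non_hispanic"
"P002",1000,53.4296034045689,5,"male","black","non_hispanic"
"P002",2000,50.5034508614167,5,"male","black","non_hispanic"
"P002",4000,46.6951720336623,5,"male","black","non_hispanic"
"P002",8000,50.8455843919618,5,"male","black","non_hispanic"
"P003",250,63.6921637796702,16,"female","white","non_hispanic"
"P003",500,67.8579317034311,16,"female","white","non_hispanic"
"P003",1000,66.5358034998315,16,"female","white","non_hispanic"
"P003",2000,64.306814716179,16,"female","white","non_hispanic"
"P003",4000,102.869027432511,16,"female","white","non_hispanic"
"P003",8000,120,16,"female","white","non_hispanic"
"P004",250,-10,1,"male","white","non_hispanic"
"P004",500,-5.39792107931796,1,"male","white","non_hispanic"
"P004",1000,-5.60874112742962,1,"male","white","non_hispanic"
"P004",2000,-7.74324154986812,1,"male","white","non_hispanic"
"P004",4000,24.3702214410765,1,"male","white","non_hispanic"
"P004",8000,52.0279486090159,1,"male","white","non_hispanic"
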