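volunteer_id,gender,age_bin,race,trust_response
V0001,female,18-25,black,yes
V0002,male,26-35,white,yes
V0003,female,36-45,other,no
V0004,male,46-55,black,not_sure
V0005,female,56-65,white,yes
V0006,male,65+,other,yes
V0007,female,18-25,black,no
V0008,male,26-35,white,not_sure
V0009,female,36-45,other,yes
V0010,male,46-55,black,yes
V0011,female,56-65,white,no
V0012,male,65+,other,not_sure
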