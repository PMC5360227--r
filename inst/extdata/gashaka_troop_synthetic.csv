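id,sex,age_class,excluded_reason
AM1,male,adult,none
AM2,male,adult,none
AM3,male,adult,none
AM4,male,adult,unhabituated_immigrant
AF1,female,adult,none
AF2,female,adult,none
AF3,female,adult,none
AF4,female,adult,none
AF5,female,adult,none
AF6,female,adult,none
AF7,female,adult,none
AF8,female,adult,shy_of_observers
SF1,female,subadult,none
SF2,female,subadult,none
SF3,female,subadult,none
SF4,female,subadult,none
SM1,male,subadult,none
JM1,male,juvenile,none
JM2,male,juvenile,none
JM3,male,juvenile,none
JM4,male,juvenile,none
JM5,male,juvenile,none
JM6,male,juvenile,none
JM7,male,juvenile,none
JM8,male,juvenile,none
JF1,female,juvenile,none
JF2,female,juvenile,none
IN1,male,infant,dependent_infant
IN2,female,infant,dependent_infant
IN3,female,infant,dependent_infant
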