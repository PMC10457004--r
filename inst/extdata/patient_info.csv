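subject_id,sex,age,imaging_diagnosis,affected_side,time_to_acquisition
P1,Male,72,Cerebral hemorrhage in right frontal lobe,right,6d 3.8h
P2,Male,48,Hemorrhage in right outer capsule area and basal ganglia area,right,9.2h
P3,Male,75,Cerebral contusion and laceration of left frontotemporal lobe with subdural and extradural hematoma,left,2d 3.1h
P4,Male,59,Left frontal lobe hemorrhage,left,5d 21.7h
P5,Male,64,Cerebral infarction in right hemisphere,right,2d 16.4h
P6,Female,48,Left frontal lobe edema,left,1d 23.3h
P7,Male,52,Right cerebellar hemisphere hemorrhage,right,1d 16.1h
P8,Male,54,Subdural hematoma of right frontal lobe with contusion and laceration of left temporal lobe,right,10d 3.5h
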