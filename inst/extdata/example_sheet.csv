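event_id,event_type,date,onset_s,offset_s,condition,actor,target,behaviour,intensity,context,through_mesh,reaction,initiator,visibility_ok,interventions,intervention_undetermined
AG001,aggression,2020-06-01,1000,1030,outdoor,To,Dm,chase,medium,spontaneous,FALSE,avoidance,,,,FALSE
AF001,affiliation,2020-06-01,1060,,outdoor,Dm,To,touch_body,,,,,Dm,TRUE,,
AG002,aggression,2020-06-03,2000,2040,indoor,To,Ta,gentle_push,low,weaning,FALSE,nonaggressive_cease,,,,FALSE
AG003,aggression,2020-06-03,6000,6030,indoor,Su,Dm,chase+bite,high,food,TRUE,avoidance,,,To:peaceful:Dm:TRUE,FALSE
AF002,affiliation,2020-06-03,6100,,indoor,Dm,Ei,contact_sitting+touch_body,,,,,Ei,TRUE,,
AF003,affiliation,2020-06-04,6500,,indoor,Dm,Su,play,,,,,Dm,TRUE,,
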